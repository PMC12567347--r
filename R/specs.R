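#' Packaged final population model specifications
#'
#' The final adult PK/PD and paediatric PD population parameter sets ship with
#' the package as YAML configs (`inst/extdata/adult_final.yaml`,
#' `paediatric_final.yaml`); these accessors read them into
#' [population_spec()] objects. They are the default generating truth of the
#' synthetic-study generators and the reference point of the parameter
#' recovery suite.
#'
#' @return a [population_spec()].
#' @export
adult_final_spec <- function() {
  read_population_spec(system.file("extdata", "adult_final.yaml",
                                   package = "ratiopkpd", mustWork = TRUE))
}

#' @rdname adult_final_spec
#' @export
paediatric_final_spec <- function() {
  read_population_spec(system.file("extdata", "paediatric_final.yaml",
                                   package = "ratiopkpd", mustWork = TRUE))
}

#' Structural models of the final adult and paediatric analyses
#' @return a [model_spec()].
#' @export
adult_final_model <- function() {
  model_spec(kind = "pkpd", absorption = "transit", disposition = "2cmt",
             pd_link = "effect_compartment", inhibition = "full",
             hill = "estimated")
}

#' @rdname adult_final_model
#' @export
paediatric_final_model <- function() {
  model_spec(kind = "pd_obsconc", inhibition = "full", hill = "fixed1")
}
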