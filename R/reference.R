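#' Published centromeric epimutation rate estimates for N. crassa
#'
#' Reference point estimates and 95% bootstrap intervals of spontaneous
#' methylation gain (alpha) and loss (beta) rates in centromeric regions of
#' the Neurospora crassa MA experiment, per sequence context and site class
#' (single cytosines: per cytosine per mitosis; DMRs: per 100-bp bin per
#' mitosis). These values serve as simulation defaults and as targets for
#' parameter-recovery checks.
#'
#' @return data.frame with columns context, site_class, alpha, alpha_lower,
#'   alpha_upper, beta, beta_lower, beta_upper
#' @export
published_rate_estimates <- function() {
  read.table(system.file("extdata", "centromeric_rate_estimates.tsv",
                         package = "epimutMA", mustWork = TRUE),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
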