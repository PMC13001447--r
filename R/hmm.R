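#' Fit a two-state methylation HMM to one sample's counts
#'
#' A hidden Markov model over cytosines ordered by genomic position within
#' each chromosome, with two hidden states (unmethylated, methylated) and
#' binomial emissions: the methylated read count at a site follows
#' Binomial(total, theta_state). Parameters (emission levels and the 2x2
#' transition matrix between adjacent sites) are estimated by
#' expectation-maximisation; chromosomes are treated as independent chains
#' started from the stationary distribution. Transition probabilities are
#' distance-independent (site-index chain). Zero-depth sites carry no
#' emission evidence and pass through the chain.
#'
#' @param meth,total integer vectors of methylated/total read counts
#' @param chrom chromosome of each site (sites must be position-sorted
#'   within chromosome)
#' @param context single context label recorded in the model
#' @param theta_init initial emission levels (unmethylated, methylated)
#' @param trans_init initial probability of staying in the same state
#' @param max_iter,tol EM stopping rule (log-likelihood improvement)
#' @param min_sites minimum number of sites with depth >= 1
#' @return an object of class `methylation_hmm` with elements `theta`
#'   (ordered emission levels), `A` (transition matrix), `loglik`,
#'   `iterations`, `converged`, `context`
#' @export
fit_methylation_hmm <- function(meth, total, chrom, context = "all",
                                theta_init = c(0.02, 0.8),
                                trans_init = 0.9,
                                max_iter = 500L, tol = 1e-6,
                                min_sites = 100L) {
  stopifnot(length(meth) == length(total), length(chrom) == length(meth))
  if (all(total == 0)) stopf("all sites have zero depth")
  if (sum(total >= 1) < min_sites)
    stopf("need at least %d sites with depth >= 1 (got %d)",
          min_sites, sum(total >= 1))
  ends <- cumsum(rle(as.character(chrom))$lengths)
  A0 <- matrix(c(trans_init, 1 - trans_init, 1 - trans_init, trans_init),
               2, 2, byrow = TRUE)
  fit <- hmm_em_binom(as.integer(meth), as.integer(total),
                      as.integer(ends), as.numeric(theta_init), A0,
                      as.integer(max_iter), tol)
  if (!fit$converged)
    warnf("EM did not converge in %d iterations; returning best-so-far model",
          max_iter)
  structure(list(theta = as.numeric(fit$theta), A = fit$A,
                 loglik = fit$loglik, iterations = fit$iterations,
                 converged = fit$converged, context = context),
            class = "methylation_hmm")
}

#' @export
print.methylation_hmm <- function(x, ...) {
  cat(sprintf(
    "methylation HMM (%s): levels u=%.4f m=%.4f, stay-prob u=%.3f m=%.3f, logLik %.1f (%d EM iters%s)\n",
    x$context, x$theta[1], x$theta[2], x$A[1, 1], x$A[2, 2], x$loglik,
    x$iterations, if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Posterior-decode per-site methylation states for one sample
#'
#' Runs the forward-backward algorithm under a fitted model and assigns each
#' site the more probable hidden state. Sites with zero depth are reported
#' as missing (`NA`), not imputed.
#'
#' @param meth,total,chrom as in [fit_methylation_hmm()]
#' @param model a fitted `methylation_hmm`
#' @param context context of the sites; must match the model's context
#' @return integer vector: 1 methylated, 0 unmethylated, `NA` missing
#' @export
call_states <- function(meth, total, chrom, model, context = model$context) {
  stopifnot(is(model, "methylation_hmm"))
  if (!identical(context, model$context))
    stopf("context mismatch: sites are %s but model was fitted for %s",
          context, model$context)
  ends <- cumsum(rle(as.character(chrom))$lengths)
  fb <- hmm_forward_backward(as.integer(meth), as.integer(total),
                             as.integer(ends), model$theta, model$A)
  st <- as.integer(fb$gamma[, 2] > 0.5)
  st[total == 0] <- NA_integer_
  st
}

#' Call methylation states for every sample of a methylome set
#'
#' For each sample and each sequence context present, fits a per-sample HMM
#' (unless a prefitted model is supplied) and posterior-decodes the states.
#'
#' @param mset a [methylome_set()]
#' @param context contexts to call (`"all"` = each context separately)
#' @param model optional prefitted `methylation_hmm` reused for all samples
#' @param ... passed to [fit_methylation_hmm()]
#' @return the methylome set with its `state` matrix filled in
#' @export
call_methylation_states <- function(mset, context = "all", model = NULL, ...) {
  ctxs <- if (identical(context, "all")) unique(mset$sites$context) else context
  state <- mset$state %||% matrix(NA_integer_, nrow(mset$sites),
                                  nrow(mset$samples),
                                  dimnames = list(NULL, mset$samples$sample_id))
  for (ctx in ctxs) {
    rows <- which(mset$sites$context == ctx)
    if (!length(rows)) next
    chrom <- mset$sites$chrom[rows]
    for (j in seq_len(ncol(state))) {
      mm <- if (is.null(model))
        fit_methylation_hmm(mset$meth[rows, j], mset$total[rows, j], chrom,
                            context = ctx, ...)
      else model
      state[rows, j] <- call_states(mset$meth[rows, j], mset$total[rows, j],
                                    chrom, mm, context = mm$context)
    }
  }
  mset$state <- state
  mset
}
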