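# Global sensitivity: Latin hypercube sampling over parameters and protein
# abundances, partial rank correlation coefficients (PRCC) with p-values.

#' Latin hypercube sample around nominal values
#'
#' Each parameter's n draws occupy distinct equal-probability strata of a
#' uniform range `nominal * (1 +/- range_frac)` (linear scale).
#'
#' @param nominal named vector of nominal values.
#' @param n number of samples.
#' @param range_frac half-width of the uniform range as a fraction of the
#'   nominal (default 0.5, i.e. +/-50%).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return n x p matrix with parameter columns.
#' @export
lhs_sample <- function(nominal, n, range_frac = 0.5, seed) {
  stopifnot(n >= length(nominal) + 2)
  set.seed(seed)
  u <- lhs::randomLHS(n, length(nominal))
  lo <- nominal * (1 - range_frac)
  hi <- nominal * (1 + range_frac)
  m <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(m) <- names(nominal)
  m
}

#' Partial rank correlation coefficients with p-values
#'
#' All variables are rank-transformed; the PRCC of parameter j with the
#' output is the correlation of the residuals of (parameter_j ~ other
#' parameters) and (output ~ other parameters).  The p-value uses
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` with `k = p - 1` conditioning
#' variables.  The default implementation computes all coefficients at
#' once through the inverse of the joint rank-correlation matrix;
#' `method = "residual"` runs the explicit per-parameter regressions and
#' is kept as the brute-force cross-check.
#'
#' @param samples n x p matrix of sampled inputs.
#' @param output numeric vector of model outputs (length n).
#' @param method "matrix" (default) or "residual".
#' @return data.frame with `parameter`, `prcc`, `p_value`.
#' @export
prcc <- function(samples, output, method = c("matrix", "residual")) {
  method <- match.arg(method)
  if (any(apply(samples, 2, function(x) length(unique(x)) == 1)))
    stop("constant column in samples: ",
         colnames(samples)[apply(samples, 2, function(x)
           length(unique(x)) == 1)][1])
  n <- nrow(samples); p <- ncol(samples)
  rs <- apply(samples, 2, rank)
  ry <- rank(output)
  r <- if (method == "matrix") {
    cm <- cor(cbind(rs, ry))
    pm <- tryCatch(solve(cm), error = function(e)
      stop("rank-deficient regression; collinear columns in samples"))
    -pm[seq_len(p), p + 1] / sqrt(diag(pm)[seq_len(p)] * pm[p + 1, p + 1])
  } else {
    vapply(seq_len(p), function(j) {
      others <- rs[, -j, drop = FALSE]
      ex <- stats::lm.fit(cbind(1, others), rs[, j])$residuals
      ey <- stats::lm.fit(cbind(1, others), ry)$residuals
      cor(ex, ey)
    }, 0)
  }
  k <- p - 1
  tt <- r * sqrt((n - 2 - k) / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * pt(abs(tt), df = n - 2 - k, lower.tail = FALSE)
  data.frame(parameter = colnames(samples), prcc = unname(r),
             p_value = unname(pv), row.names = NULL)
}

#' Significance-filtered PRCC values
#'
#' PRCCs with `p >= alpha` are set to zero, the convention used for
#' heatmap reporting.
#'
#' @param prcc_df output of [prcc()].
#' @param alpha significance threshold (default 0.01).
#' @return the data.frame with an added `prcc_filtered` column.
#' @export
prcc_filter <- function(prcc_df, alpha = 0.01) {
  prcc_df$prcc_filtered <- ifelse(prcc_df$p_value < alpha, prcc_df$prcc, 0)
  prcc_df
}

#' LHS-PRCC sensitivity pipeline over the pathway model
#'
#' Samples all free parameters and the scalable protein abundances within
#' +/-`range_frac` of nominal, simulates the HGF reference condition for
#' each sample, and computes significance-filtered PRCCs for the requested
#' readouts at the requested times (15 and 120 min by default, the early
#' and steady-state timepoints).  Failed simulations are dropped with a
#' logged count.
#'
#' @param model a `pathway_model`.
#' @param n number of LHS samples (desk-scale default 300; the study scale
#'   is 5000).
#' @param readouts readout names.
#' @param times evaluation times in minutes.
#' @param range_frac sampling half-width (default 0.5).
#' @param seed RNG seed.
#' @param include_abundances also vary protein totals (default TRUE).
#' @param alpha significance threshold for filtering.
#' @param base base [condition()].
#' @return object of class `sensitivity_result`: list with `samples`,
#'   `outputs` (matrix, columns readout@time), `prcc` (long data.frame),
#'   `n_failed`.
#' @export
sensitivity_pipeline <- function(model, n = 300,
                                 readouts = c("pAkt", "pERK",
                                              "pMet_surface",
                                              "pMet_internal"),
                                 times = c(15, 120), range_frac = 0.5,
                                 seed = 1, include_abundances = TRUE,
                                 alpha = 0.01,
                                 base = condition(hgf = 40,
                                                  output_times = c(15, 120))) {
  free <- model$parameters$name[model$parameters$free]
  nominal <- model_params(model)[free]
  if (include_abundances) {
    is_rate <- vapply(model$scalable, function(x)
      length(x) == 1 && x %in% model$parameters$name, TRUE)
    ab_names <- names(model$scalable)[!is_rate]
    totals <- vapply(ab_names, function(g)
      sum(model$species$initial[model$species$name %in%
                                  model$scalable[[g]]]), 0)
    names(totals) <- paste0("abundance_", ab_names)
    nominal <- c(nominal, totals)
  }
  samples <- lhs_sample(nominal, n, range_frac, seed)
  outs <- matrix(NA_real_, n, length(readouts) * length(times))
  colnames(outs) <- as.vector(outer(readouts, times, paste, sep = "@"))
  n_failed <- 0L
  for (i in seq_len(n)) {
    x <- samples[i, ]
    m <- set_params(model, x[free])
    if (include_abundances) {
      for (g in sub("^abundance_", "",
                    grep("^abundance_", names(x), value = TRUE))) {
        sp <- model$scalable[[g]]
        tot0 <- sum(model$species$initial[model$species$name %in% sp])
        fac <- x[[paste0("abundance_", g)]] / tot0
        cur <- setNames(model$species$initial[model$species$name %in% sp] *
                          fac, sp)
        m <- set_initial(m, cur)
      }
    }
    tr <- tryCatch(simulate_condition(m, base), error = function(e) NULL)
    if (is.null(tr)) { n_failed <- n_failed + 1L; next }
    for (rd in readouts) for (tv in times)
      outs[i, paste0(rd, "@", tv)] <- readout_values(tr, rd, tv)
  }
  ok <- stats::complete.cases(outs)
  res <- do.call(rbind, lapply(colnames(outs), function(cn) {
    df <- prcc_filter(prcc(samples[ok, , drop = FALSE], outs[ok, cn]),
                      alpha)
    df$output <- cn
    df
  }))
  structure(list(samples = samples, outputs = outs, prcc = res,
                 n_failed = n_failed), class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("LHS-PRCC sensitivity:", nrow(x$samples), "samples,",
      length(unique(x$prcc$output)), "outputs,", x$n_failed,
      "failed simulations\n")
  invisible(x)
}
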