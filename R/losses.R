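#' Normalized and log-scaled k-space losses
#'
#' Self-supervised training compares reconstructed and measured multicoil
#' k-space on an index subset.  Conventional terms are the normalized l2
#' (NRMSE) and l1 (NMAE) residual ratios.  Because k-space energy is dominated
#' by a few low-frequency coefficients, these ratios under-weight the
#' high-frequency residuals that carry edges and fine structure.  The
#' log-scaled terms compress the residual dynamic range,
#' \deqn{L_p = \frac{\| \log(1 + |\hat y - y|) \|_p^p}{\| \log(1 + |y|) \|_p^p},}
#' re-balancing gradient contributions toward high frequencies.  Note the
#' p-th-power norms in the log-scaled form (vs the plain ratio of norms for
#' the conventional terms), and that log scaling is deliberately not
#' scale-invariant: inputs are normalized upstream (max `|A^H y| = 1`).
#'
#' @name losses
NULL

subset_residual <- function(y_hat, y, subset) {
  d <- dim(y)
  if (!all(dim(y_hat) == d)) stop("k-space shape mismatch")
  C <- d[3]
  # grid subset applies to every coil
  idx <- as.vector(outer(subset, (seq_len(C) - 1L) * (d[1] * d[2]), `+`))
  list(r = y_hat[idx] - y[idx], yv = y[idx], idx = idx)
}

#' Conventional normalized loss (NRMSE / NMAE)
#'
#' `|| P(y_hat - y) ||_p / || P y ||_p` over complex residual magnitudes on
#' the subset; a fraction in `[0, ...)` (multiply by 100 for percent).
#'
#' @param y_hat,y complex multicoil k-space arrays (ny x nx x C).
#' @param subset linear grid indices (column-major, 1-based) of the loss set.
#' @param p 1 or 2.
#' @return nonnegative scalar.
#' @export
normalized_loss <- function(y_hat, y, subset, p = 2) {
  if (length(subset) == 0) stop("empty loss subset")
  sr <- subset_residual(y_hat, y, subset)
  den <- if (p == 2) l2norm(sr$yv) else sum(Mod(sr$yv))
  if (den == 0) stop("reference k-space is zero on the loss subset")
  num <- if (p == 2) l2norm(sr$r) else sum(Mod(sr$r))
  num / den
}

#' Log-scaled normalized loss
#'
#' `|| log(1 + |y_hat - y|) ||_p^p / || log(1 + |y|) ||_p^p` on the subset
#' (natural log, p-th-power norms).
#'
#' @inheritParams normalized_loss
#' @return nonnegative scalar.
#' @export
log_scaled_loss <- function(y_hat, y, subset, p = 2) {
  if (length(subset) == 0) stop("empty loss subset")
  sr <- subset_residual(y_hat, y, subset)
  den <- sum(log1p(Mod(sr$yv))^p)
  if (den == 0) stop("reference k-space is zero on the loss subset")
  sum(log1p(Mod(sr$r))^p) / den
}

#' Loss specification
#'
#' @param kind `"conventional"` (NMAE + NRMSE), `"log_scaled"` (log-l1 +
#'   log-l2), or `"combined"` (all four).
#' @param weights optional named nonnegative weights per term; default unit.
#' @return a `loss_spec` list with elements `kind`, `terms`, `weights`.
#' @export
loss_spec <- function(kind = c("conventional", "log_scaled", "combined"),
                      weights = NULL) {
  kind <- match.arg(kind)
  terms <- switch(kind,
    conventional = c("l1", "l2"),
    log_scaled = c("log_l1", "log_l2"),
    combined = c("l1", "l2", "log_l1", "log_l2"))
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(terms)), terms)
  stopifnot(all(terms %in% names(weights)), all(weights > 0))
  structure(list(kind = kind, terms = terms, weights = weights[terms]),
            class = "loss_spec")
}

loss_term <- function(term, y_hat, y, subset) {
  switch(term,
    l1 = normalized_loss(y_hat, y, subset, 1),
    l2 = normalized_loss(y_hat, y, subset, 2),
    log_l1 = log_scaled_loss(y_hat, y, subset, 1),
    log_l2 = log_scaled_loss(y_hat, y, subset, 2),
    stop("unknown loss term"))
}

#' Composite training loss
#'
#' Weighted sum of the selected conventional / log-scaled terms.
#'
#' @inheritParams normalized_loss
#' @param spec a [loss_spec()].
#' @return nonnegative scalar.
#' @export
composite_loss <- function(y_hat, y, subset, spec = loss_spec("combined")) {
  sum(vapply(spec$terms,
             function(t) spec$weights[[t]] * loss_term(t, y_hat, y, subset),
             numeric(1)))
}

# Complex gradient (dL/dRe + i dL/dIm) of the composite loss wrt y_hat,
# nonzero only on the subset.  phase(0) treated as 0.
composite_loss_grad <- function(y_hat, y, subset, spec) {
  sr <- subset_residual(y_hat, y, subset)
  r <- sr$r
  m <- Mod(r)
  ph <- ifelse(m > 0, r / m, 0i)
  g <- complex(length(r))
  for (t in spec$terms) {
    w <- spec$weights[[t]]
    gt <- switch(t,
      l1 = {
        den <- sum(Mod(sr$yv))
        ph / den
      },
      l2 = {
        den <- l2norm(sr$yv)
        nr <- l2norm(r)
        if (nr == 0) complex(length(r)) else r / (nr * den)
      },
      log_l1 = {
        den <- sum(log1p(Mod(sr$yv)))
        ph / ((1 + m) * den)
      },
      log_l2 = {
        den <- sum(log1p(Mod(sr$yv))^2)
        ph * (2 * log1p(m) / (1 + m)) / den
      })
    g <- g + w * gt
  }
  out <- array(0i, dim(y))
  out[sr$idx] <- g
  out
}
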