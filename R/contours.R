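#' Highest-density-region contours of the (q, a) parameter cloud
#'
#' Bins all per-step parameter estimates of a condition into a bivariate
#' histogram normalized to probability mass, and finds, for each requested
#' level, the density threshold whose super-level set is the smallest set of
#' bins containing at least that fraction of the total mass (highest-density
#' region). At a level's threshold the whole tied density class is included,
#' which keeps the region independent of bin enumeration order. 1D marginal
#' histograms over q and a are returned alongside.
#'
#' @param pairs Data frame of per-step estimates with columns
#'   `q_hat`/`a_hat` (or `q`/`a`), e.g. `tidy()` of an [infer_cells()] fit.
#' @param q_domain,a_domain Histogram domains; pairs outside are excluded
#'   and counted. Reporting conventionally restricts q to \[0, 1\] even
#'   though the model (and inference grid) allow negative persistence.
#' @param bins Length-2 integer vector: number of bins in q and a.
#' @param levels Probability-mass levels for the contours.
#' @return An object of class `prw_contours`: `q_edges`, `a_edges`, `mass`
#'   (bins-q x bins-a probability-mass matrix), `thresholds` (tibble
#'   `level`, `threshold`, `mass_covered`, `n_bins`), `q_marginal`,
#'   `a_marginal`, `n_used`, `n_excluded`.
#' @examples
#' pts <- data.frame(q_hat = runif(500, 0.2, 0.8), a_hat = runif(500, 1, 4))
#' ct <- joint_density_contours(pts)
#' ct$thresholds
#' @export
joint_density_contours <- function(pairs, q_domain = c(0, 1),
                                   a_domain = c(0, 10), bins = c(50L, 50L),
                                   levels = c(0.5, 0.8, 0.95)) {
  nm <- names(pairs)
  qcol <- if ("q_hat" %in% nm) "q_hat" else if ("q" %in% nm) "q" else
    abort("`pairs` needs a q_hat (or q) column")
  acol <- if ("a_hat" %in% nm) "a_hat" else if ("a" %in% nm) "a" else
    abort("`pairs` needs an a_hat (or a) column")
  q <- as.numeric(pairs[[qcol]]); a <- as.numeric(pairs[[acol]])
  inside <- q >= q_domain[1] & q <= q_domain[2] &
    a >= a_domain[1] & a <= a_domain[2] & is.finite(q) & is.finite(a)
  n_excluded <- sum(!inside)
  q <- q[inside]; a <- a[inside]
  if (length(q) == 0) abort("no (q, a) pairs inside the domain")
  q_edges <- seq(q_domain[1], q_domain[2], length.out = bins[1] + 1L)
  a_edges <- seq(a_domain[1], a_domain[2], length.out = bins[2] + 1L)
  qi <- findInterval(q, q_edges, rightmost.closed = TRUE)
  ai <- findInterval(a, a_edges, rightmost.closed = TRUE)
  counts <- matrix(0, bins[1], bins[2])
  tab <- table(factor(qi, levels = seq_len(bins[1])),
               factor(ai, levels = seq_len(bins[2])))
  counts[] <- as.numeric(tab)
  mass <- counts / sum(counts)
  v <- sort(unique(as.vector(mass)), decreasing = TRUE)
  total_at <- vapply(v, function(th) sum(mass[mass >= th]), numeric(1))
  thresholds <- lapply(levels, function(lv) {
    th <- v[which(total_at >= lv)[1]]
    tibble(level = lv, threshold = th,
           mass_covered = sum(mass[mass >= th]),
           n_bins = sum(mass >= th))
  })
  structure(list(
    q_edges = q_edges, a_edges = a_edges, mass = mass,
    thresholds = bind_rows(thresholds),
    q_marginal = tibble(q_mid = (q_edges[-1] + q_edges[-length(q_edges)]) / 2,
                        mass = rowSums(mass)),
    a_marginal = tibble(a_mid = (a_edges[-1] + a_edges[-length(a_edges)]) / 2,
                        mass = colSums(mass)),
    n_used = length(q), n_excluded = n_excluded, levels = levels
  ), class = "prw_contours")
}

#' @export
print.prw_contours <- function(x, ...) {
  cat("<prw_contours>", x$n_used, "pairs binned (", x$n_excluded,
      "outside domain )\n")
  print(x$thresholds)
  invisible(x)
}

#' @export
tidy.prw_contours <- function(x, ...) {
  qm <- (x$q_edges[-1] + x$q_edges[-length(x$q_edges)]) / 2
  am <- (x$a_edges[-1] + x$a_edges[-length(x$a_edges)]) / 2
  tidyr::expand_grid(q_mid = qm, a_mid = am) %>%
    mutate(mass = as.vector(t(x$mass))) %>%
    select("q_mid", "a_mid", "mass")
}
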