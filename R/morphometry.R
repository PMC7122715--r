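# Morphometric validation of airway trees: Strahler and Horsfield ordering,
# branching / diameter / length ratios, branching angles, per-generation
# distributions and terminal (acinus) counts.

#' Strahler and Horsfield orders of every branch
#'
#' Both schemes start at 1 on terminal branches and work rootward.
#' Strahler: a parent takes the larger child order when the children differ,
#' otherwise that order plus one. Horsfield: a parent is one plus the
#' maximum child order. Strahler order never exceeds Horsfield order.
#'
#' @param tree an [airway_tree].
#' @return Integer vector of per-branch orders (index = branch id).
#' @export
strahler_orders <- function(tree) {
  traverse_orders(tree, function(ch_orders) {
    m <- max(ch_orders)
    if (sum(ch_orders == m) >= 2L) m + 1L else m
  })
}

#' @rdname strahler_orders
#' @export
horsfield_orders <- function(tree) {
  traverse_orders(tree, function(ch_orders) max(ch_orders) + 1L)
}

traverse_orders <- function(tree, combine) {
  b <- tree$branches
  kids <- children_list(tree)
  ord <- integer(nrow(b))
  for (i in order(b$generation, decreasing = TRUE)) {
    ch <- kids[[i]]
    ord[i] <- if (length(ch) == 0L) 1L else combine(ord[ch])
  }
  ord
}

#' Branching ratio from branch counts per order
#'
#' The branching ratio RB is the antilog of the magnitude of the slope of
#' the least-squares regression of log branch count on order: counts grow
#' geometrically toward low orders and RB is the per-order factor. At least
#' three populated orders are required.
#'
#' @param counts named or plain vector of branch counts, one per consecutive
#'   order (order 1 first).
#' @return The ratio RB (>= 1 for any tree).
#' @export
branching_ratio <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) < 3L)
    stop("need at least 3 populated orders to fit a branching ratio")
  ord <- seq_along(counts)
  exp(abs(unname(stats::coef(stats::lm(log(counts) ~ ord))[2L])))
}

#' Diameter or length ratio across orders
#'
#' Antilog of the regression slope of log mean value (diameter or length)
#' on order: the per-order growth factor of the mean, the standard
#' morphometric RD / RL estimator.
#'
#' @param values_per_order list of numeric vectors, one per consecutive
#'   order (order 1 first), each with at least one value.
#' @return The ratio (antilog of the slope magnitude).
#' @export
ratio_per_order <- function(values_per_order) {
  mu <- vapply(values_per_order, function(v) mean(v, na.rm = TRUE), numeric(1L))
  keep <- is.finite(mu) & mu > 0
  if (sum(keep) < 3L)
    stop("need at least 3 populated orders to fit a per-order ratio")
  ord <- seq_along(mu)[keep]
  exp(abs(unname(stats::coef(stats::lm(log(mu[keep]) ~ ord))[2L])))
}

# Alternative estimator: mean of successive per-order ratios.
ratio_successive <- function(values_per_order) {
  mu <- vapply(values_per_order, function(v) mean(v, na.rm = TRUE), numeric(1L))
  mu <- mu[is.finite(mu) & mu > 0]
  if (length(mu) < 2L) stop("need at least 2 populated orders")
  mean(mu[-1L] / mu[-length(mu)])
}

#' Branching angles at every bifurcation
#'
#' For each non-root branch, the angle (degrees) between its chord direction
#' and its parent's chord direction at the bifurcation. Both children of a
#' bifurcation contribute one angle each. Zero-length branches are skipped
#' with a warning.
#'
#' @param tree an [airway_tree].
#' @return data.frame with `branch`, `parent`, `generation` and
#'   `angle_deg`.
#' @export
branching_angles <- function(tree) {
  b <- tree$branches
  nonroot <- b$id[!is.na(b$parent)]
  dirs <- t(vapply(seq_len(nrow(b)), function(i) {
    p <- tree$polylines[[i]]
    p[nrow(p), ] - p[1L, ]
  }, numeric(3L)))
  lens <- sqrt(rowSums(dirs^2))
  zero <- lens < 1e-9
  if (any(zero[nonroot]) || any(zero[stats::na.omit(b$parent[nonroot])]))
    warning("zero-length branches skipped in angle computation")
  ang <- vapply(nonroot, function(i) {
    p <- b$parent[i]
    if (zero[i] || zero[p]) return(NA_real_)
    angle_deg(dirs[i, ], dirs[p, ])
  }, numeric(1L))
  out <- data.frame(branch = nonroot, parent = b$parent[nonroot],
                    generation = b$generation[nonroot], angle_deg = ang)
  out[!is.na(out$angle_deg), ]
}

#' Morphometric summary of an airway tree
#'
#' Computes the macroscopic structural statistics used to validate
#' generated bronchial trees: terminal (acinus) count; branch counts per
#' Strahler and per Horsfield order; branching ratios `RB_S`, `RB_H`;
#' diameter ratios `RD_S`, `RD_H` and length ratios `RL_S`, `RL_H` (with
#' their per-order spreads); the mean per-generation diameter rate of
#' decline `RD` (mean over generations of mean-diameter(g+1) /
#' mean-diameter(g), with its sd); and pooled branching-angle mean and sd.
#'
#' @param tree an [airway_tree]; diameters are needed for the diameter
#'   statistics (others are computed regardless).
#' @param method ratio estimator: `"regression"` (default, antilog of the
#'   log-linear slope) or `"successive"` (mean of successive order ratios).
#' @return A `morphometry_summary` list.
#' @export
summarize_morphometry <- function(tree, method = c("regression", "successive")) {
  method <- match.arg(method)
  est <- if (method == "regression") ratio_per_order else ratio_successive
  b <- tree$branches
  s_ord <- strahler_orders(tree)
  h_ord <- horsfield_orders(tree)
  kids <- children_list(tree)
  n_terminal <- sum(lengths(kids) == 0L)
  count_s <- tabulate(s_ord)
  count_h <- tabulate(h_ord)
  per_order <- function(vals, ord) split(vals, factor(ord, levels = seq_len(max(ord))))
  have_d <- !anyNA(b$diameter)
  rb_s <- branching_ratio(count_s)
  rb_h <- branching_ratio(count_h)
  rl_s <- est(per_order(b$length, s_ord))
  rl_h <- est(per_order(b$length, h_ord))
  rd_s <- if (have_d) est(per_order(b$diameter, s_ord)) else NA_real_
  rd_h <- if (have_d) est(per_order(b$diameter, h_ord)) else NA_real_
  # per-generation diameter decline: mean_{g} mean-d(g+1) / mean-d(g)
  rd_gen <- NA_real_; rd_gen_sd <- NA_real_
  if (have_d) {
    mu_g <- vapply(split(b$diameter, b$generation), mean, numeric(1L))
    if (length(mu_g) >= 2L) {
      rr <- mu_g[-1L] / mu_g[-length(mu_g)]
      rd_gen <- mean(rr)
      rd_gen_sd <- stats::sd(rr)
    }
  }
  ang <- branching_angles(tree)
  structure(list(
    n_terminal = n_terminal,
    counts_strahler = count_s,
    counts_horsfield = count_h,
    RB_S = rb_s, RB_H = rb_h,
    RD_S = rd_s, RD_H = rd_h,
    RL_S = rl_s, RL_H = rl_h,
    RD_generation = rd_gen, RD_generation_sd = rd_gen_sd,
    theta_mean = mean(ang$angle_deg), theta_sd = stats::sd(ang$angle_deg),
    generation_lengths = split(b$length, b$generation),
    generation_diameters = if (have_d) split(b$diameter, b$generation) else NULL,
    generation_angles = split(ang$angle_deg, ang$generation)),
    class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat("morphometry_summary\n")
  cat(sprintf("  terminal branches (acini): %d\n", x$n_terminal))
  cat(sprintf("  RB_H %.3f  RB_S %.3f\n", x$RB_H, x$RB_S))
  if (!is.na(x$RD_H))
    cat(sprintf("  RD_H %.4f  RD_S %.4f\n", x$RD_H, x$RD_S))
  cat(sprintf("  RL_H %.3f  RL_S %.3f\n", x$RL_H, x$RL_S))
  if (!is.na(x$RD_generation))
    cat(sprintf("  diameter decline per generation: %.3f +/- %.3f\n",
                x$RD_generation, x$RD_generation_sd))
  cat(sprintf("  branching angle: %.2f +/- %.2f degrees\n",
              x$theta_mean, x$theta_sd))
  invisible(x)
}
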