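# Branch diameter laws: the symmetric power law and the asymmetric
# diameter/angle branching relations.

#' Symmetric power-law airway diameter
#'
#' `d_z = d0 * 2^(-z/3)`: the diameter of a generation-z branch under
#' symmetric dichotomous branching with cube-law flow conservation, anchored
#' at the trachea diameter `d0` (generation 0). The per-generation ratio is
#' exactly `2^(1/3)`.
#'
#' @param d0 trachea diameter, mm (> 0).
#' @param z generation (>= 0); vectorized.
#' @return Diameter(s) in mm.
#' @export
murray_diameter <- function(d0, z) {
  stopifnot_scalar_num(d0, "d0")
  if (d0 <= 0) stop("'d0' must be positive")
  if (any(z < 0)) stop("'z' must be >= 0")
  d0 * 2^(-z / 3)
}

#' Child diameters and branching angles at an asymmetric bifurcation
#'
#' Child diameters satisfy the parent-child conservation law
#' `d0^n = d1^n + d2^n` for a given asymmetry ratio `d1/d2 >= 1`
#' (exponent `n = 2` by default, the printed area-conservation form; `n = 3`
#' gives the classic cube law, under which an equal split reproduces
#' [murray_diameter()] exactly). Branching angles solve the sine relation
#' `d0^2 / sin(t1 + t2) = d1^2 / sin(t1) = d2^2 / sin(t2)`,
#' which is the law of sines of a triangle with sides `(d0^2, d1^2, d2^2)`;
#' the closed-form solution is the law of cosines on that triangle. The
#' system only has a root with angles in (0, 90) when
#' `d1^2 + d2^2 > d0^2` strictly — under exact area conservation the
#' triangle is degenerate and the angle system admits only the zero angles,
#' so `kamiya_children()` then returns `theta1 = theta2 = 0` with a warning.
#'
#' @param d0 parent diameter, mm (> 0).
#' @param r asymmetry ratio `d1/d2` (>= 1); `theta1` belongs to the larger
#'   child `d1`.
#' @param exponent conservation-law exponent `n` (default 2).
#' @return List with `d1`, `d2` (mm) and `theta1`, `theta2` (degrees).
#' @export
kamiya_children <- function(d0, r = 1, exponent = 2) {
  stopifnot_scalar_num(d0, "d0"); stopifnot_scalar_num(r, "r")
  if (d0 <= 0) stop("'d0' must be positive")
  if (r < 1) stop("'r' must be >= 1 (d1 is the larger child)")
  d2 <- d0 / (1 + r^exponent)^(1 / exponent)
  d1 <- r * d2
  ang <- tryCatch(solve_branching_angles(d0, d1, d2),
                  error = function(e) {
                    warning(conditionMessage(e))
                    list(theta1 = 0, theta2 = 0)
                  })
  list(d1 = d1, d2 = d2, theta1 = ang$theta1, theta2 = ang$theta2)
}

#' @rdname kamiya_children
#' @param d1,d2 child diameters, mm.
#' @export
solve_branching_angles <- function(d0, d1, d2) {
  s0 <- d0^2; s1 <- d1^2; s2 <- d2^2
  if (s1 + s2 <= s0 + 1e-12 * s0)
    stop(sprintf(paste0("no branching angles in (0, 90) degrees: the sine ",
                        "relation requires d1^2 + d2^2 > d0^2 ",
                        "(got %.6g + %.6g vs %.6g)"), s1, s2, s0))
  # law of cosines on the triangle with sides (s0, s1, s2): theta1 is the
  # angle opposite side s1 = d1^2, theta2 opposite s2 = d2^2
  c1 <- (s0^2 + s2^2 - s1^2) / (2 * s0 * s2)
  c2 <- (s0^2 + s1^2 - s2^2) / (2 * s0 * s1)
  if (abs(c1) >= 1 || abs(c2) >= 1)
    stop("no branching angles in (0, 90) degrees: degenerate diameter triple")
  t1 <- acos(c1) * 180 / pi
  t2 <- acos(c2) * 180 / pi
  if (t1 >= 90 || t2 >= 90)
    stop("no branching angles in (0, 90) degrees for this diameter triple")
  list(theta1 = t1, theta2 = t2)
}

#' Assign branch diameters over a whole tree
#'
#' `mode = "murray"`: diameter is a function of generation only, via
#' [murray_diameter()]. `mode = "kamiya"`: recursive descent from the
#' trachea; at every bifurcation the asymmetry ratio is taken from the
#' terminal counts of the two child subtrees (ratio `(n_big/n_small)^(1/n)`,
#' a flow-proportional proxy), the larger subtree receiving the larger
#' child diameter via [kamiya_children()]. Child diameters never exceed the
#' parent's in either mode.
#'
#' @param tree an [airway_tree].
#' @param d0 trachea diameter, mm.
#' @param mode `"murray"` (default) or `"kamiya"`.
#' @param exponent conservation exponent for kamiya mode (default 2).
#' @return The tree with `branches$diameter` filled in.
#' @export
assign_diameters <- function(tree, d0, mode = c("murray", "kamiya"),
                             exponent = 2) {
  stopifnot(inherits(tree, "airway_tree"))
  if (missing(d0) || is.null(d0)) stop("'d0' (trachea diameter, mm) is required")
  stopifnot_scalar_num(d0, "d0")
  mode <- match.arg(mode)
  b <- tree$branches
  if (mode == "murray") {
    b$diameter <- murray_diameter(d0, b$generation)
  } else {
    nterm <- subtree_terminal_counts(tree)
    kids <- children_list(tree)
    diam <- rep(NA_real_, nrow(b))
    root <- b$id[is.na(b$parent)]
    diam[root] <- d0
    # breadth-first so parents are set before children
    frontier <- root
    while (length(frontier)) {
      nxt <- integer(0L)
      for (p in frontier) {
        ch <- kids[[p]]
        if (length(ch) == 0L) next
        if (length(ch) == 1L) {
          diam[ch] <- diam[p]  # pass-through: no bifurcation, no narrowing
        } else {
          o <- order(nterm[ch], decreasing = TRUE)
          big <- ch[o[1L]]; rest <- ch[o[-1L]]
          r <- (nterm[big] / nterm[rest[1L]])^(1 / exponent)
          kc <- suppressWarnings(kamiya_children(diam[p], r, exponent))
          diam[big] <- min(kc$d1, diam[p])
          diam[rest] <- min(kc$d2, diam[p])
        }
        nxt <- c(nxt, ch)
      }
      frontier <- nxt
    }
    b$diameter <- diam
  }
  tree$branches <- b
  tree
}

# Number of terminal branches below (and including) each branch.
subtree_terminal_counts <- function(tree) {
  b <- tree$branches
  kids <- children_list(tree)
  n <- nrow(b)
  cnt <- integer(n)
  # process deepest generations first so children are done before parents
  for (i in order(b$generation, decreasing = TRUE)) {
    ch <- kids[[i]]
    cnt[i] <- if (length(ch) == 0L) 1L else sum(cnt[ch])
  }
  cnt
}
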