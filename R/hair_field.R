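#' Define a range-fractionated hair field
#'
#' A hair field is a row of `n_hairs` proprioceptive hairs whose receptive
#' fields tile the joint-angle interval `[theta_min, theta_max]` with uniform
#' size and spacing, adjacent fields overlapping by `overlap` degrees.
#' Orientation selects the deflection law: a `"positive"` hair is undeflected
#' below its receptive field and fully deflected (90 degrees) above it; a
#' `"negative"` hair is the mirror image (fully deflected below, undeflected
#' above), modelling the opposing hair row of the same joint.
#'
#' @param n_hairs Number of hairs (>= 1).
#' @param theta_min,theta_max Joint-angle sensitivity bounds (deg).
#' @param overlap Receptive-field overlap between adjacent hairs (deg); must
#'   be non-negative and smaller than the per-hair spacing.
#' @param orientation `"positive"` or `"negative"`.
#' @return An object of class `hair_field`.
#' @examples
#' hair_field(5, 0, 92, overlap = 4)
#' @export
hair_field <- function(n_hairs, theta_min, theta_max, overlap = 0.1,
                       orientation = c("positive", "negative")) {
  orientation <- match.arg(orientation)
  n_hairs <- as.integer(n_hairs)
  stopifnot(n_hairs >= 1)
  if (theta_max <= theta_min) stop("`theta_max` must exceed `theta_min`")
  spacing <- (theta_max - theta_min) / n_hairs
  if (overlap < 0 || overlap >= spacing) {
    stop("`overlap` must lie in [0, (theta_max - theta_min)/n_hairs)")
  }
  structure(
    list(n_hairs = n_hairs, theta_min = theta_min, theta_max = theta_max,
         overlap = overlap, orientation = orientation),
    class = "hair_field"
  )
}

#' @export
print.hair_field <- function(x, ...) {
  cat(sprintf("<hair_field> %d %s hairs over [%g, %g] deg, overlap %g deg\n",
              x$n_hairs, x$orientation, x$theta_min, x$theta_max, x$overlap))
  invisible(x)
}

#' Receptive-field edges of each hair in a field
#'
#' Interior edges place hair `i` over the `i`-th of `n_hairs` equal sub-ranges,
#' widened by half the overlap on each side; the first hair's lower edge and
#' the last hair's upper edge are forced to the field bounds so that the union
#' of receptive fields covers the sensitivity range exactly.
#'
#' @param field A [hair_field()].
#' @return A tibble with columns `hair`, `rf0` and `rf90` (deg): the joint
#'   angles at which deflection starts (0 deg) and saturates (90 deg) for a
#'   positive-orientation hair; for negative orientation the deflection runs
#'   from 90 deg at `rf0` down to 0 deg at `rf90`.
#' @examples
#' receptive_field_edges(hair_field(5, 0, 92, overlap = 4))
#' @export
receptive_field_edges <- function(field) {
  stopifnot(inherits(field, "hair_field"))
  i <- seq_len(field$n_hairs)
  span <- field$theta_max - field$theta_min
  spacing <- span / field$n_hairs
  rf0 <- spacing * (i - 1) + field$theta_min - field$overlap / 2
  rf90 <- spacing * i + field$theta_min + field$overlap / 2
  rf0[1] <- field$theta_min
  rf90[field$n_hairs] <- field$theta_max
  if (any(rf90 - rf0 <= 0)) stop("zero-width receptive field")
  tibble::tibble(hair = i, rf0 = rf0, rf90 = rf90)
}

#' Per-hair deflection angles for given joint angles
#'
#' Maps joint angle linearly onto hair deflection within each hair's receptive
#' field and clamps outside it, so deflections always lie in `[0, 90]`
#' degrees. Joint angles outside the field's sensitivity range are legal: the
#' hairs simply saturate.
#'
#' @param field A [hair_field()].
#' @param theta Joint angles (deg), any length.
#' @return A numeric matrix, `length(theta)` rows by `n_hairs` columns, of
#'   deflection angles in degrees.
#' @examples
#' f <- hair_field(5, 0, 92, overlap = 4)
#' hair_angles(f, c(0, 45, 90))
#' @export
hair_angles <- function(field, theta) {
  stopifnot(inherits(field, "hair_field"))
  edges <- receptive_field_edges(field)
  theta <- as.numeric(theta)
  frac <- outer(theta, edges$rf0, "-") /
    matrix(edges$rf90 - edges$rf0, nrow = length(theta),
           ncol = field$n_hairs, byrow = TRUE)
  frac <- pmin(pmax(frac, 0), 1)
  phi <- if (field$orientation == "positive") 90 * frac else 90 * (1 - frac)
  dimnames(phi) <- list(NULL, paste0("h", edges$hair))
  phi
}

#' Convert hair deflection to afferent input current
#'
#' Deflection angles are multiplied by the mechanotransduction gain
#' (pA per degree), yielding currents in the nA range for full deflection.
#'
#' @param phi Deflection angles (deg): a numeric vector or matrix, or a
#'   protocol trace (data frame with columns `t` and `theta`) whose angle
#'   column is treated as the hair deflection.
#' @param gain Current per degree of deflection (pA/deg), positive.
#' @return Same shape as `phi`; for a trace input, a tibble with columns `t`
#'   and `I` (pA) ready for [integrate_adex()].
#' @examples
#' hair_currents(90, gain = 50) # 4500 pA = 4.5 nA
#' @export
hair_currents <- function(phi, gain = 50) {
  if (gain <= 0) stop("`gain` must be positive")
  if (is.data.frame(phi)) {
    if (!all(c("t", "theta") %in% names(phi))) {
      stop("trace input needs columns `t` and `theta`")
    }
    return(tibble::tibble(t = phi$t, I = phi$theta * gain))
  }
  phi * gain
}

#' Build a bi-directional hair plate for one joint
#'
#' A hair plate pairs two opposing hair fields around the joint's resting
#' angle (the midpoint of its working range). In the basic arrangement the
#' negative-orientation field covers the lower half and the positive field the
#' upper half, meeting at the resting angle with a small overlap so that the
#' innermost hair of each field is partially deflected at rest. In the
#' `extended` arrangement both fields span the full working range (needed for
#' whole-range velocity encoding); only the hairs whose receptive fields lie
#' within each field's original half-range keep a connection to the position
#' interneurons (`position_mask`), the supplementary hairs feeding the
#' velocity chain alone.
#'
#' @param working_range Length-2 numeric, the joint's working range (deg).
#' @param n_hairs Hairs per field.
#' @param overlap Receptive-field overlap, also the inter-field overlap at
#'   rest (deg).
#' @param gain Mechanotransduction gain (pA/deg); validated against the
#'   plausible 10–150 pA/deg range.
#' @param extended Build the extended bi-directional plate?
#' @return An object of class `hair_plate` with elements `field_neg`,
#'   `field_pos`, `resting_angle`, `gain`, `extended`, and logical masks
#'   `mask_neg`/`mask_pos` marking position-wired hairs.
#' @examples
#' hair_plate(c(0, 180), n_hairs = 50, extended = TRUE)
#' @export
hair_plate <- function(working_range, n_hairs = 50, overlap = 0.1,
                       gain = 50, extended = FALSE) {
  stopifnot(length(working_range) == 2)
  lo <- working_range[1]; hi <- working_range[2]
  if (hi <= lo) stop("`working_range` must be increasing")
  if (gain < 10 || gain > 150) {
    stop("`gain` outside the plausible 10-150 pA/deg range")
  }
  rest <- (lo + hi) / 2
  if (extended) {
    field_neg <- hair_field(n_hairs, lo, hi, overlap, "negative")
    field_pos <- hair_field(n_hairs, lo, hi, overlap, "positive")
    eps <- 1e-9
    mask_neg <- receptive_field_edges(field_neg)$rf90 <= rest + overlap / 2 + eps
    mask_pos <- receptive_field_edges(field_pos)$rf0 >= rest - overlap / 2 - eps
  } else {
    field_neg <- hair_field(n_hairs, lo, rest + overlap / 2, overlap, "negative")
    field_pos <- hair_field(n_hairs, rest - overlap / 2, hi, overlap, "positive")
    mask_neg <- rep(TRUE, n_hairs)
    mask_pos <- rep(TRUE, n_hairs)
  }
  # inter-field overlap at rest, from the (original) half-range bounds
  olhf <- (rest + overlap / 2) - (rest - overlap / 2)
  structure(
    list(field_neg = field_neg, field_pos = field_pos,
         resting_angle = rest, gain = gain, extended = extended,
         overlap = overlap, olhf = olhf,
         mask_neg = mask_neg, mask_pos = mask_pos),
    class = "hair_plate"
  )
}

#' @export
print.hair_plate <- function(x, ...) {
  cat(sprintf("<hair_plate>%s rest %g deg, gain %g pA/deg\n",
              if (x$extended) " extended," else "", x$resting_angle, x$gain))
  cat("  neg: "); print(x$field_neg)
  cat("  pos: "); print(x$field_pos)
  cat(sprintf("  position-wired hairs: %d neg + %d pos\n",
              sum(x$mask_neg), sum(x$mask_pos)))
  invisible(x)
}

#' Inter-field overlap of a hair plate at its resting angle
#'
#' The overlap is the width of the joint-angle interval covered by both
#' fields around rest: the negative field's upper sensitivity bound minus the
#' positive field's lower bound. It keeps a low but non-zero afferent rate at
#' the resting posture.
#'
#' @param plate A [hair_plate()].
#' @return Overlap in degrees.
#' @examples
#' overlap_at_rest(hair_plate(c(0, 180), overlap = 4))
#' @export
overlap_at_rest <- function(plate) {
  stopifnot(inherits(plate, "hair_plate"))
  if (plate$extended) plate$olhf
  else plate$field_neg$theta_max - plate$field_pos$theta_min
}

#' Deflection of all hairs of a plate, with plate-level indexing
#'
#' Hairs 1..n are the negative field, hairs n+1..2n the positive field,
#' matching raster-plot numbering (e.g. hairs 1-50 and 51-100 for the default
#' 50-hair fields).
#'
#' @param plate A [hair_plate()].
#' @param theta Joint angles (deg).
#' @return Matrix `length(theta)` x `2 * n_hairs` of deflection angles.
#' @export
plate_angles <- function(plate, theta) {
  stopifnot(inherits(plate, "hair_plate"))
  phi <- cbind(hair_angles(plate$field_neg, theta),
               hair_angles(plate$field_pos, theta))
  colnames(phi) <- paste0("h", seq_len(ncol(phi)))
  phi
}
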