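# 3D spot colocalization. Spots are manually placed cell-body centres; a
# channel-A spot counts as double-labelled when it can be matched to a
# channel-B spot closer than the distance threshold (strictly less than,
# e.g. 3.5 um for medulla neurons, 2.5 um for the tightly packed T4 cell
# bodies). Matching is one-to-one, built greedily by ascending pair
# distance, which prevents a single B spot from validating several A spots.

#' Construct a 3D spot set
#'
#' @param points numeric matrix or data frame with columns \code{x_um},
#'   \code{y_um}, \code{z_um} (micrometres); zero rows allowed.
#' @param channel channel label.
#' @param specimen_id optional specimen identifier.
#' @return object of class \code{spot_set}.
#' @export
spot_set <- function(points, channel = "unnamed", specimen_id = NA_character_) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must have 3 columns (x_um, y_um, z_um)")
  colnames(points) <- c("x_um", "y_um", "z_um")
  if (nrow(points) > 0) {
    if (any(!is.finite(points))) stop("spot coordinates must be finite")
    if (anyDuplicated(round(points, 9))) {
      stop("duplicate spots (within 1e-9 um) are not allowed")
    }
  }
  structure(list(points = points, channel = channel,
                 specimen_id = specimen_id),
            class = "spot_set")
}

#' Colocalize two spot sets under a distance threshold
#'
#' Candidate pairs are all (A, B) spot pairs at distance strictly less
#' than \code{threshold_um}. In the default \code{"one_to_one"} mode a
#' matching is built greedily by ascending distance (ties broken by lower
#' A index, then lower B index), each spot used at most once. The
#' \code{"any_within"} mode instead counts every A spot with at least one
#' B spot inside the threshold, for sensitivity analysis against the
#' one-to-one rule.
#'
#' @param a,b [spot_set()]s; \code{a} must be nonempty.
#' @param threshold_um distance cutoff in micrometres (> 0); matches
#'   require distance < threshold (strict).
#' @param mode \code{"one_to_one"} (default) or \code{"any_within"}.
#' @return object of class \code{coloc_result}: \code{matches} (data
#'   frame \code{a_index}, \code{b_index}, \code{distance}),
#'   \code{percent_a_colocalized}, \code{threshold_um}, \code{mode},
#'   \code{n_a}, \code{n_b}.
#' @examples
#' a <- spot_set(matrix(runif(30, 0, 50), ncol = 3))
#' colocalize(a, a, threshold_um = 3.5)$percent_a_colocalized # 100
#' @export
colocalize <- function(a, b, threshold_um,
                       mode = c("one_to_one", "any_within")) {
  stopifnot(inherits(a, "spot_set"), inherits(b, "spot_set"))
  mode <- match.arg(mode)
  if (!(threshold_um > 0)) stop("threshold_um must be > 0")
  n_a <- nrow(a$points)
  n_b <- nrow(b$points)
  if (n_a == 0) stop("spot set 'a' is empty")
  matches <- data.frame(a_index = integer(0), b_index = integer(0),
                        distance = numeric(0))
  if (n_b > 0) {
    d2 <- outer(rowSums(a$points^2), rowSums(b$points^2), "+") -
      2 * a$points %*% t(b$points)
    d <- sqrt(pmax(d2, 0))
    cand <- which(d < threshold_um, arr.ind = TRUE)
    if (nrow(cand)) {
      dist_c <- d[cand]
      o <- order(dist_c, cand[, 1], cand[, 2])
      cand <- cand[o, , drop = FALSE]
      dist_c <- dist_c[o]
      if (mode == "one_to_one") {
        used_a <- logical(n_a); used_b <- logical(n_b)
        keep <- logical(nrow(cand))
        for (i in seq_len(nrow(cand))) {
          ai <- cand[i, 1]; bi <- cand[i, 2]
          if (!used_a[ai] && !used_b[bi]) {
            used_a[ai] <- TRUE; used_b[bi] <- TRUE
            keep[i] <- TRUE
          }
        }
        matches <- data.frame(a_index = cand[keep, 1],
                              b_index = cand[keep, 2],
                              distance = dist_c[keep])
      } else { # any_within: nearest B for every A inside the threshold
        first <- !duplicated(cand[, 1])
        matches <- data.frame(a_index = cand[first, 1],
                              b_index = cand[first, 2],
                              distance = dist_c[first])
      }
      matches <- matches[order(matches$a_index), , drop = FALSE]
      rownames(matches) <- NULL
    }
  }
  structure(
    list(matches = matches,
         percent_a_colocalized = 100 * nrow(matches) / n_a,
         threshold_um = threshold_um, mode = mode, n_a = n_a, n_b = n_b),
    class = "coloc_result"
  )
}

#' Summarise double-labelled percentages across specimens
#'
#' Specimen-level percentages (not pooled cells) are averaged; the error
#' is the SEM over specimens. With a single specimen the SEM is undefined
#' and reported as 0 with \code{single_specimen = TRUE}.
#'
#' @param results list of [colocalize()] results, or a numeric vector of
#'   per-specimen percentages.
#' @return list with \code{mean}, \code{sem}, \code{per_specimen},
#'   \code{n_specimens}, \code{single_specimen}.
#' @export
percent_double_labeled <- function(results) {
  pct <- if (is.numeric(results)) {
    as.numeric(results)
  } else {
    vapply(results, function(r) {
      stopifnot(inherits(r, "coloc_result"))
      r$percent_a_colocalized
    }, numeric(1))
  }
  if (length(pct) < 1) stop("need at least one specimen")
  single <- length(pct) == 1
  list(mean = mean(pct),
       sem = if (single) 0 else sd(pct) / sqrt(length(pct)),
       per_specimen = pct,
       n_specimens = length(pct),
       single_specimen = single)
}
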