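#' Normalized Shannon entropy of a count vector
#'
#' The class-balance entropy core: `H(p) / log(n_classes)` with
#' `p = counts / sum(counts)` and the convention `0 * log 0 = 0`. The value
#' is base-invariant and lies in `[0, 1]`; it is 1 for a uniform
#' distribution and 0 when a single class holds every count. `n_classes`
#' defaults to `length(counts)` but may be larger, so classes that are
#' entirely absent from the counts still depress the balance score.
#'
#' @param counts Nonnegative numeric vector of per-class counts (at least
#'   one positive).
#' @param n_classes Size of the class universe used for normalization.
#' @return A number in `[0, 1]`. For a one-class universe the distribution
#'   is trivially balanced and the value is defined as 1.
#' @examples
#' normalized_entropy(c(2, 1, 1)) # 1.5 bits / log2(3)
#' @export
normalized_entropy <- function(counts, n_classes = length(counts)) {
  if (any(counts < 0)) rlang::abort("`counts` must be nonnegative")
  total <- sum(counts)
  if (total <= 0) rlang::abort("`counts` must have a positive total")
  if (n_classes < length(counts[counts > 0])) {
    rlang::abort("`n_classes` smaller than the number of occupied classes")
  }
  if (n_classes == 1) return(1)
  p <- counts[counts > 0] / total
  -sum(p * log(p)) / log(n_classes)
}

#' Class-Presence Coverage of a support split
#'
#' The mean, over every class in the pool's universe, of the fraction of
#' support images that contain at least one box of that class. A class is
#' either present in an image or not; box multiplicity does not matter.
#' Classes absent from every support image contribute 0 to the mean, so the
#' universe of the *pool* (not just of the support set) is the frame of
#' reference.
#'
#' @param pool An [od_pool()].
#' @param support_ids Character vector of support image ids (non-empty,
#'   drawn from the pool).
#' @return A fraction in `[0, 1]`.
#' @seealso [class_balance_entropy()], [support_spread_score()]
#' @export
class_presence_coverage <- function(pool, support_ids) {
  stopifnot(is_od_pool(pool))
  support_ids <- as.character(support_ids)
  if (length(support_ids) == 0) {
    rlang::abort("empty support set: coverage is undefined")
  }
  if (length(pool$classes) == 0) rlang::abort("pool has an empty class universe")
  unknown <- setdiff(support_ids, pool$images$image_id)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown support image_id: ",
                        paste(unknown, collapse = ", ")))
  }
  boxes <- pool$boxes[pool$boxes$image_id %in% support_ids, ]
  present <- unique(boxes[, c("image_id", "class")])
  per_class <- table(factor(present$class, levels = pool$classes))
  mean(as.integer(per_class) / length(support_ids))
}

#' Class-Balance Entropy of a support split
#'
#' The Shannon entropy of the distribution of support *boxes* over classes,
#' normalized by its maximum `log |C|`, where `|C|` is the size of the
#' pool's full class universe. Missing classes therefore depress the score.
#' See [normalized_entropy()] for conventions (base invariance, one-class
#' degenerate case).
#'
#' @inheritParams class_presence_coverage
#' @return A fraction in `[0, 1]`.
#' @export
class_balance_entropy <- function(pool, support_ids) {
  stopifnot(is_od_pool(pool))
  counts <- class_box_counts(pool, as.character(support_ids))$n_boxes
  if (sum(counts) == 0) {
    rlang::abort("support set contains no boxes: balance is undefined")
  }
  normalized_entropy(counts, n_classes = length(pool$classes))
}

#' Support-Spread Score
#'
#' The selection criterion among optimal splits: the product of
#' Class-Presence Coverage and Class-Balance Entropy,
#' `SSS = CPC x CBE`. High values require the support images to jointly
#' cover all classes often (CPC) *and* to carry a balanced box distribution
#' over classes (CBE).
#'
#' @inheritParams class_presence_coverage
#' @return A one-row tibble of class `od_split_score` with columns `cpc`,
#'   `cbe`, `sss`.
#' @examples
#' cfg <- fixture_config(n_images = 8, sources = "demo", seed = 3)
#' pool <- generate_dataset(cfg, render = FALSE)$pool
#' support_spread_score(pool, pool$images$image_id[1:3])
#' @export
support_spread_score <- function(pool, support_ids) {
  new_split_score(class_presence_coverage(pool, support_ids),
                  class_balance_entropy(pool, support_ids))
}

#' Combine coverage and balance components into a split score
#'
#' @param cpc,cbe Fractions in `[0, 1]`.
#' @return A one-row `od_split_score` tibble with `sss = cpc * cbe`.
#' @export
new_split_score <- function(cpc, cbe) {
  stopifnot(length(cpc) == 1, length(cbe) == 1,
            cpc >= 0, cpc <= 1, cbe >= 0, cbe <= 1)
  out <- tibble::tibble(cpc = as.numeric(cpc), cbe = as.numeric(cbe),
                        sss = as.numeric(cpc) * as.numeric(cbe))
  class(out) <- c("od_split_score", class(out))
  out
}
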