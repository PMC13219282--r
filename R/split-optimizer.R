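#' Configuration for few-shot split optimization
#'
#' Defaults mirror the benchmark construction conditions: 10 support
#' (example) and 53 test (reference) images per source and 1000 shuffled
#' orderings.
#'
#' @param n_support Support images to select per source.
#' @param n_test Test images per source; each per-source pool must contain
#'   exactly `n_support + n_test` images.
#' @param trials Number of shuffled-ordering trials `T`.
#' @param base_seed Integer; trial `t` (0-based) shuffles with seed
#'   `base_seed + t`.
#' @param lambda_surplus Weight of the surplus-support-box penalty in the
#'   Phase-2 scalarized objective.
#' @param min_support_boxes_per_class Optional per-class floor on support
#'   boxes (0 disables the constraint).
#' @return A list of class `od_split_config`.
#' @export
split_config <- function(n_support = 10, n_test = 53, trials = 1000,
                         base_seed = 0, lambda_surplus = 1,
                         min_support_boxes_per_class = 0) {
  stopifnot(n_support >= 1, n_test >= 0, trials >= 1,
            lambda_surplus >= 0, min_support_boxes_per_class >= 0)
  structure(list(n_support = as.integer(n_support),
                 n_test = as.integer(n_test),
                 trials = as.integer(trials),
                 base_seed = as.integer(base_seed),
                 lambda_surplus = as.numeric(lambda_surplus),
                 min_support_boxes_per_class =
                   as.integer(min_support_boxes_per_class)),
            class = "od_split_config")
}

# Per-source static problem data.
#   d: per-image count of distinct classes present (the coverage increment)
#   cost: per-image Phase-2 cost sum_c (w_c + lambda) * b_ci with
#         w_c = 1 / (total source boxes of class c)
#   B: images x classes box-count matrix (source-present classes only)
source_problem <- function(pool, lambda) {
  ids <- pool$images$image_id
  cls <- intersect(pool$classes, unique(pool$boxes$class))
  B <- matrix(0L, nrow = length(ids), ncol = length(cls),
              dimnames = list(ids, cls))
  if (nrow(pool$boxes) > 0 && length(cls) > 0) {
    tab <- table(factor(pool$boxes$image_id, levels = ids),
                 factor(pool$boxes$class, levels = cls))
    B[] <- as.integer(tab)
  }
  total <- colSums(B)
  w <- if (length(cls) > 0) 1 / total else numeric(0)
  list(ids = ids,
       d = as.integer(rowSums(B > 0)),
       cost = as.numeric(B %*% (w + lambda)),
       B = B, w = w, total = total,
       const = sum(w * total))  # sum_c w_c * pool boxes of c
}

#' Phase 1: maximal class-image coverage
#'
#' Selects exactly `n_support` images of a single-source pool maximizing the
#' coverage `Cov = sum_c sum_i a_ci x_i`, where `a_ci = 1` iff image `i`
#' contains at least one box of class `c` — i.e. the count of
#' (class, support-image) presence pairs. Because the coverage contribution
#' of an image is independent of the other selections, the certified optimum
#' is attained by taking the `n_support` images with the most distinct
#' classes; `ordering` breaks ties among equally-covering images (emulating
#' a branch-and-bound solver's sensitivity to variable order: the optimum is
#' ordering-invariant, the selected set need not be).
#'
#' @param pool A single-source [od_pool()].
#' @param n_support Number of images to select.
#' @param ordering Optional permutation of `seq_len(n_images)` giving the
#'   variable order; defaults to the pool order.
#' @return A list with `cov_star` (integer certified optimum) and
#'   `support_ids`.
#' @export
phase1_max_coverage <- function(pool, n_support, ordering = NULL) {
  stopifnot(is_od_pool(pool))
  n <- nrow(pool$images)
  if (n_support > n) {
    rlang::abort(paste0("n_support (", n_support, ") exceeds pool size (",
                        n, ")"))
  }
  prob <- source_problem(pool, lambda = 0)
  ordering <- check_ordering(ordering, n)
  pos <- order(ordering)  # pos[i] = rank of image i in the ordering
  sel <- order(-prob$d, pos)[seq_len(n_support)]
  list(cov_star = as.integer(sum(prob$d[sel])),
       support_ids = prob$ids[sel])
}

check_ordering <- function(ordering, n) {
  if (is.null(ordering)) return(seq_len(n))
  ordering <- as.integer(ordering)
  if (!identical(sort(ordering), seq_len(n))) {
    rlang::abort("`ordering` must be a permutation of seq_len(n_images)")
  }
  ordering
}

#' Phase 2: surplus-minimizing refinement at locked coverage
#'
#' Among all `n_support`-subsets attaining the Phase-1 coverage `cov_star`
#' (and, if requested, at least `min_support` boxes of every source class),
#' maximizes the scalarized objective
#' `sum_c w_c * r_c - lambda * sum_c s_c`, where `s_c` is the number of
#' support boxes of class `c`, `r_c` the reference (non-support) boxes of
#' `c`, and `w_c = 1 / (source boxes of c)` the inverse-frequency weight.
#' Equivalently it minimizes a per-image linear cost, which is solved
#' exactly: by dynamic programming over (selected count, coverage) when the
#' per-class floor is off, and by an exhaustive depth-first search with
#' admissible pruning when it is on. Both routes return the certified
#' optimum; `ordering` again only breaks ties.
#'
#' @inheritParams phase1_max_coverage
#' @param cov_star Coverage value from Phase 1 on the same pool.
#' @param lambda Surplus penalty weight.
#' @param min_support Per-class minimum support-box count (0 = off).
#' @return A list with `support_ids`, `objective` (the certified maximum of
#'   the scalarized objective) and `cov_star`.
#' @export
phase2_refine <- function(pool, n_support, cov_star, lambda = 1,
                          min_support = 0, ordering = NULL) {
  stopifnot(is_od_pool(pool))
  n <- nrow(pool$images)
  if (n_support > n) rlang::abort("n_support exceeds pool size")
  prob <- source_problem(pool, lambda)
  ordering <- check_ordering(ordering, n)
  if (min_support > 0 && ncol(prob$B) > 0) {
    # per-class attainability: best case takes the n_support largest counts
    for (k in seq_len(ncol(prob$B))) {
      best <- sum(sort(prob$B[, k], decreasing = TRUE)[seq_len(n_support)])
      if (best < min_support) {
        rlang::abort(paste0("min_support_boxes_per_class infeasible for ",
                            "class '", colnames(prob$B)[k], "'"))
      }
    }
  }
  sel <- if (min_support > 0) {
    phase2_dfs(prob, n_support, cov_star, min_support, ordering)
  } else {
    phase2_dp(prob, n_support, cov_star, ordering)
  }
  if (is.null(sel)) {
    rlang::abort("coverage constraint infeasible at cov_star (phase mismatch)")
  }
  list(support_ids = prob$ids[sel],
       objective = prob$const - sum(prob$cost[sel]),
       cov_star = as.integer(sum(prob$d[sel])))
}

# Exact DP: choose n items with sum(d) == cov_star minimizing sum(cost).
# Items are processed in the shuffled ordering; on cost ties the backtrack
# prefers taking the earlier item, so the selected optimal vertex depends on
# the ordering while the optimum itself does not.
phase2_dp <- function(prob, n_support, cov_star, ordering) {
  idx <- ordering
  d <- prob$d[idx]; cost <- prob$cost[idx]
  N <- length(idx); V <- cov_star
  # dp[[i]][k+1, v+1] = min cost selecting k items with coverage v from i..N
  inf <- Inf
  dp <- vector("list", N + 1L)
  base <- matrix(inf, n_support + 1L, V + 1L)
  base[1L, 1L] <- 0
  dp[[N + 1L]] <- base
  for (i in N:1) {
    nxt <- dp[[i + 1L]]
    cur <- nxt  # skip item i
    if (d[i] <= V) {
      # take item i: shift k by 1 and v by d[i]
      shifted <- matrix(inf, n_support + 1L, V + 1L)
      shifted[2L:(n_support + 1L), (d[i] + 1L):(V + 1L)] <-
        nxt[1L:n_support, 1L:(V + 1L - d[i]), drop = FALSE] + cost[i]
      cur <- pmin(cur, shifted)
    } else if (d[i] == 0 && V == 0) {
      shifted <- matrix(inf, n_support + 1L, V + 1L)
      shifted[2L:(n_support + 1L), 1L] <- nxt[1L:n_support, 1L] + cost[i]
      cur <- pmin(cur, shifted)
    }
    dp[[i]] <- cur
  }
  if (!is.finite(dp[[1L]][n_support + 1L, V + 1L])) return(NULL)
  # backtrack, preferring "take" on (near-)ties
  tol <- 1e-9
  sel <- integer(0); k <- n_support; v <- V
  for (i in seq_len(N)) {
    if (k == 0L && v == 0L) break
    take_val <- if (k >= 1L && v >= d[i]) {
      dp[[i + 1L]][k, v - d[i] + 1L] + cost[i]
    } else inf
    skip_val <- dp[[i + 1L]][k + 1L, v + 1L]
    if (take_val <= skip_val + tol) {
      sel <- c(sel, idx[i]); k <- k - 1L; v <- v - d[i]
    }
  }
  sel
}

# Exhaustive DFS for the per-class minimum-support variant; exact, with
# admissible pruning (cost lower bound, coverage reachability, per-class
# remaining-box reachability).
phase2_dfs <- function(prob, n_support, cov_star, min_support, ordering) {
  idx <- ordering
  d <- prob$d[idx]; cost <- prob$cost[idx]
  B <- prob$B[idx, , drop = FALSE]
  N <- length(idx); C <- ncol(B)
  # suffix helpers
  suf_max_d <- suf_min_d <- suf_min_cost <- vector("list", N + 1L)
  for (i in (N + 1L):1L) {
    tail_d <- if (i <= N) d[i:N] else integer(0)
    tail_c <- if (i <= N) cost[i:N] else numeric(0)
    suf_max_d[[i]] <- cumsum(c(0L, sort(tail_d, decreasing = TRUE)))
    suf_min_d[[i]] <- cumsum(c(0L, sort(tail_d)))
    suf_min_cost[[i]] <- cumsum(c(0, sort(tail_c)))
  }
  suf_B <- apply(rbind(B, matrix(0L, 1L, C)), 2L,
                 function(col) rev(cumsum(rev(col))))
  suf_B <- matrix(suf_B, ncol = C)
  best <- list(cost = Inf, sel = NULL)
  rec <- function(i, k, v, s, acc, sel) {
    # k to pick, v coverage still needed, s per-class support counts so far
    if (k == 0L) {
      if (v == 0L && all(s >= min_support) && acc < best$cost - 1e-12) {
        best <<- list(cost = acc, sel = sel)
      }
      return(invisible())
    }
    if (i > N) return(invisible())
    if (N - i + 1L < k) return(invisible())
    if (v < suf_min_d[[i]][k + 1L] || v > suf_max_d[[i]][k + 1L]) {
      return(invisible())
    }
    if (acc + suf_min_cost[[i]][k + 1L] >= best$cost - 1e-12) {
      return(invisible())
    }
    need <- pmax(0L, min_support - s)
    if (any(need > suf_B[i, ])) return(invisible())
    rec(i + 1L, k - 1L, v - d[i], s + B[i, ], acc + cost[i],
        c(sel, idx[i]))
    rec(i + 1L, k, v, s, acc, sel)
  }
  rec(1L, n_support, cov_star, rep(0L, C), 0, integer(0))
  best$sel
}

#' Optimize a few-shot test/support split
#'
#' Runs the two-phase certified-exact solve independently on each source of
#' a multi-source pool, repeated over `trials` shuffled image orderings
#' (trial `t`, 0-based, shuffles with seed `base_seed + t`). Phase 1
#' maximizes class-image coverage, recording the optimum `Cov*`; Phase 2
#' locks coverage at `Cov*` and maximizes the inverse-frequency-weighted
#' reference box count minus `lambda` times the support box count. Every
#' trial's optimum is certified (trials that fail to solve would be
#' discarded and counted, mirroring a branch-and-bound backend whose
#' certificate can fail). Each surviving candidate split — the union of
#' per-source supports — is scored by [support_spread_score()] over the
#' pooled support set, and the maximum-SSS split is retained, breaking ties
#' toward the earliest trial. Deterministic given `base_seed`.
#'
#' @param pool A (possibly multi-source) [od_pool()]; each source must hold
#'   exactly `n_support + n_test` images.
#' @param config An [split_config()].
#' @return An object of class `od_split`: the winning assignment with
#'   per-source diagnostics (`cov_star`, `phase2_objective`), the pooled
#'   [support_spread_score()], the winning trial index, and solver status
#'   counts. Use [tidy()] for the per-image assignment table and
#'   [glance()] for the one-row summary.
#' @examples
#' cfg <- fixture_config(n_images = 6, sources = c("s1", "s2"), seed = 7)
#' pool <- generate_dataset(cfg, render = FALSE)$pool
#' optimize_split(pool, split_config(n_support = 2, n_test = 4, trials = 5))
#' @export
optimize_split <- function(pool, config = split_config()) {
  stopifnot(is_od_pool(pool), inherits(config, "od_split_config"))
  sources <- unique(pool$images$source)
  sub_pools <- lapply(sources, function(s) {
    pool_subset(pool, pool$images$image_id[pool$images$source == s])
  })
  names(sub_pools) <- sources
  for (s in sources) {
    n <- nrow(sub_pools[[s]]$images)
    if (n != config$n_support + config$n_test) {
      rlang::abort(paste0("source '", s, "' has ", n, " images; expected ",
                          "n_support + n_test = ",
                          config$n_support + config$n_test))
    }
  }
  probs <- lapply(sub_pools, source_problem, lambda = config$lambda_surplus)
  # presence/count matrices over the full pool for fast SSS scoring
  all_ids <- pool$images$image_id
  Ball <- matrix(0L, length(all_ids), length(pool$classes),
                 dimnames = list(all_ids, pool$classes))
  if (nrow(pool$boxes) > 0) {
    tab <- table(factor(pool$boxes$image_id, levels = all_ids),
                 factor(pool$boxes$class, levels = pool$classes))
    Ball[] <- as.integer(tab)
  }
  Pall <- Ball > 0
  n_sup_total <- config$n_support * length(sources)

  best <- NULL
  n_discarded <- 0L
  for (t in seq_len(config$trials) - 1L) {
    trial <- tryCatch({
      orderings <- withr::with_seed(config$base_seed + t, {
        lapply(sub_pools, function(p) sample.int(nrow(p$images)))
      })
      per_source <- lapply(sources, function(s) {
        p1 <- phase1_max_coverage(sub_pools[[s]], config$n_support,
                                  orderings[[s]])
        p2 <- phase2_refine(sub_pools[[s]], config$n_support, p1$cov_star,
                            lambda = config$lambda_surplus,
                            min_support = config$min_support_boxes_per_class,
                            ordering = orderings[[s]])
        list(source = s, cov_star = p1$cov_star,
             objective = p2$objective, support_ids = p2$support_ids)
      })
      per_source
    }, error = function(e) {
      if (grepl("infeasible for|exceeds pool size|expected", conditionMessage(e))) {
        rlang::abort(conditionMessage(e))  # configuration errors are fatal
      }
      NULL  # anything else: trial discarded
    })
    if (is.null(trial)) {
      n_discarded <- n_discarded + 1L
      next
    }
    support_ids <- unlist(lapply(trial, `[[`, "support_ids"),
                          use.names = FALSE)
    sup_counts <- colSums(Ball[support_ids, , drop = FALSE])
    cpc <- mean(colSums(Pall[support_ids, , drop = FALSE]) / n_sup_total)
    cbe <- if (sum(sup_counts) > 0) {
      normalized_entropy(sup_counts, n_classes = length(pool$classes))
    } else 0
    sss <- cpc * cbe
    if (is.null(best) || sss > best$sss + 1e-12) {
      best <- list(sss = sss, cpc = cpc, cbe = cbe, trial = t,
                   per_source = trial, support_ids = support_ids)
    }
  }
  if (is.null(best)) {
    rlang::abort(paste0("all ", config$trials, " trials were discarded (",
                        n_discarded, " solver failures)"))
  }
  new_od_split(pool, config, best, n_discarded)
}

new_od_split <- function(pool, config, best, n_discarded) {
  assignment <- dplyr::mutate(
    pool$images[, c("image_id", "source")],
    split = ifelse(.data$image_id %in% best$support_ids, "support", "test"))
  per_source <- purrr::map_dfr(best$per_source, function(x) {
    tibble::tibble(source = x$source, cov_star = x$cov_star,
                   phase2_objective = x$objective)
  })
  structure(list(assignment = assignment, per_source = per_source,
                 score = new_split_score(best$cpc, best$cbe),
                 winning_trial = best$trial,
                 trials = config$trials, n_discarded = n_discarded,
                 config = config),
            class = "od_split")
}

#' @export
print.od_split <- function(x, ...) {
  cat("<od_split> ", sum(x$assignment$split == "support"), " support / ",
      sum(x$assignment$split == "test"), " test images over ",
      nrow(x$per_source), " source(s)\n", sep = "")
  cat(sprintf("  SSS = %.4f (CPC = %.4f, CBE = %.4f), winning trial %d of %d\n",
              x$score$sss, x$score$cpc, x$score$cbe, x$winning_trial,
              x$trials))
  invisible(x)
}

#' @export
tidy.od_split <- function(x, ...) x$assignment

#' @export
glance.od_split <- function(x, ...) {
  tibble::tibble(cpc = x$score$cpc, cbe = x$score$cbe, sss = x$score$sss,
                 cov_star_total = sum(x$per_source$cov_star),
                 winning_trial = x$winning_trial, trials = x$trials,
                 n_discarded = x$n_discarded)
}

#' Support image ids of a split
#' @param split An `od_split`.
#' @return Character vector of support image ids.
#' @export
support_ids <- function(split) {
  stopifnot(inherits(split, "od_split"))
  split$assignment$image_id[split$assignment$split == "support"]
}

#' Brute-force split oracle
#'
#' Exhaustively enumerates every feasible per-source support subset and
#' applies the identical Phase-1 (maximal coverage), Phase-2 (maximal
#' scalarized objective at locked coverage, per-class floors respected) and
#' pooled-SSS criteria. Intended as a test oracle for [optimize_split()] on
#' small pools; refuses combinatorially large instances.
#'
#' @inheritParams optimize_split
#' @param max_subsets Refusal bound on per-source `choose(n, k)` and on the
#'   cross-source product of optimal subsets.
#' @return An `od_split`, with `winning_trial = NA`.
#' @export
brute_force_split <- function(pool, config = split_config(),
                              max_subsets = 1e5) {
  stopifnot(is_od_pool(pool), inherits(config, "od_split_config"))
  sources <- unique(pool$images$source)
  per_source <- lapply(sources, function(s) {
    sub <- pool_subset(pool, pool$images$image_id[pool$images$source == s])
    n <- nrow(sub$images)
    if (n != config$n_support + config$n_test) {
      rlang::abort(paste0("source '", s, "' has ", n, " images; expected ",
                          config$n_support + config$n_test))
    }
    if (choose(n, config$n_support) > max_subsets) {
      rlang::abort("combinatorial bound exceeded; refusing enumeration")
    }
    prob <- source_problem(pool = sub, lambda = config$lambda_surplus)
    subsets <- utils::combn(n, config$n_support, simplify = FALSE)
    cov <- vapply(subsets, function(s) sum(prob$d[s]), numeric(1))
    cov_star <- max(cov)
    cand <- subsets[cov == cov_star]
    if (config$min_support_boxes_per_class > 0 && ncol(prob$B) > 0) {
      ok <- vapply(cand, function(s) {
        all(colSums(prob$B[s, , drop = FALSE]) >=
              config$min_support_boxes_per_class)
      }, logical(1))
      if (!any(ok)) {
        rlang::abort("min_support_boxes_per_class infeasible at cov_star")
      }
      cand <- cand[ok]
    }
    obj <- vapply(cand, function(s) prob$const - sum(prob$cost[s]),
                  numeric(1))
    best_obj <- max(obj)
    optimal <- cand[obj >= best_obj - 1e-9]
    list(source = s, cov_star = as.integer(cov_star), objective = best_obj,
         optimal = lapply(optimal, function(sel) prob$ids[sel]))
  })
  n_opt <- vapply(per_source, function(x) length(x$optimal), numeric(1))
  if (prod(n_opt) > max_subsets) {
    rlang::abort("combinatorial bound exceeded; refusing enumeration")
  }
  combos <- expand.grid(lapply(n_opt, seq_len))
  best <- NULL
  for (r in seq_len(nrow(combos))) {
    sup <- unlist(lapply(seq_along(per_source), function(j) {
      per_source[[j]]$optimal[[combos[r, j]]]
    }), use.names = FALSE)
    sc <- support_spread_score(pool, sup)
    if (is.null(best) || sc$sss > best$sss + 1e-12) {
      best <- list(sss = sc$sss, cpc = sc$cpc, cbe = sc$cbe, trial = NA_integer_,
                   per_source = lapply(seq_along(per_source), function(j) {
                     x <- per_source[[j]]
                     list(source = x$source, cov_star = x$cov_star,
                          objective = x$objective,
                          support_ids = x$optimal[[combos[r, j]]])
                   }),
                   support_ids = sup)
    }
  }
  new_od_split(pool, config, best, n_discarded = 0L)
}
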