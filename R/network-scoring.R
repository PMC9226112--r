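# Mutual-predictability scoring on the weighted functional-linkage network.
#
# Each gene "predicts" a category set through its weighted neighborhood: the
# direct neighbors are ranked by edge weight and the AUC measures how well
# that ranking separates set members (positives) from non-members among the
# neighbors.  The mutual predictability of a (driver, DRG) pair is the
# geometric mean of the two directional AUCs, and the top-k pairs per driver
# category form the genetic-alteration-driven networks.

# Adjacency index: per node a data.frame(neighbor, weight) sorted by weight
# descending, gene id ascending.  Built once per network and cached on it.
build_adjacency <- function(net) {
  e <- net$edges
  nb <- data.frame(center = c(e$from, e$to),
                   neighbor = c(e$to, e$from),
                   weight = c(e$weight, e$weight),
                   stringsAsFactors = FALSE)
  nb <- nb[order(nb$center, -nb$weight, nb$neighbor), , drop = FALSE]
  split(nb[c("neighbor", "weight")], factor(nb$center, levels = net$nodes))
}

get_adjacency <- function(net) {
  adj <- attr(net, "adjacency")
  if (is.null(adj)) adj <- build_adjacency(net)
  adj
}

#' Precompute and cache the neighbor index of a network
#'
#' Optional optimization before scoring many pairs with the same network.
#'
#' @param net A [functional_network()].
#' @return The network with its adjacency index attached.
#' @export
index_network <- function(net) {
  attr(net, "adjacency") <- build_adjacency(net)
  net
}

#' Weight-ranked direct neighbors of a gene
#'
#' @param net A [functional_network()].
#' @param gene A node id.
#' @return An object of class `neighbor_ranking`: data frame
#'   (`neighbor`, `weight`) sorted by weight descending (ties broken by gene
#'   id for reproducible output; the AUC is tie-aware and order-independent),
#'   with the center gene as attribute `center`.
#' @export
neighbor_ranking <- function(net, gene) {
  if (!gene %in% net$nodes) {
    stop("gene not in network: ", gene, call. = FALSE)
  }
  adj <- get_adjacency(net)
  r <- adj[[gene]]
  if (is.null(r)) {
    r <- data.frame(neighbor = character(), weight = numeric(),
                    stringsAsFactors = FALSE)
  }
  rownames(r) <- NULL
  structure(r, class = c("neighbor_ranking", "data.frame"), center = gene)
}

#' Recovery AUC of a category set from a weighted neighbor ranking
#'
#' Positives are the set members among the neighbors.  With `n+` positives
#' and `n-` negatives the AUC is the tie-corrected Mann-Whitney statistic
#' `[sum over pos-neg pairs of 1(w_p > w_q) + 1/2 * 1(w_p = w_q)] / (n+ n-)`,
#' identical to the trapezoid area under the ROC curve swept over weight
#' cutoffs.  Undefined (`NA`) when either class is empty among the neighbors.
#'
#' @param ranking A [neighbor_ranking()].
#' @param positives Character vector: the category gene set.
#' @return The AUC in `[0, 1]`, or `NA_real_` when undefined.
#' @export
auc_recovery <- function(ranking, positives) {
  pos <- ranking$neighbor %in% positives
  npos <- sum(pos)
  nneg <- sum(!pos)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(ranking$weight, ties.method = "average")
  u <- sum(r[pos]) - npos * (npos + 1) / 2
  u / (npos * nneg)
}

#' Explicit cutoff-sweep ROC oracle for the recovery AUC
#'
#' Computes the ROC curve at every distinct weight cutoff (TPR/FPR of
#' neighbors at or above the cutoff) and integrates by the trapezoid rule.
#' Exists as an independent check of [auc_recovery()]; the two must agree to
#' floating round-off.
#'
#' @inheritParams auc_recovery
#' @return The AUC, or `NA_real_` when undefined.
#' @export
auc_bruteforce_oracle <- function(ranking, positives) {
  pos <- ranking$neighbor %in% positives
  npos <- sum(pos)
  nneg <- sum(!pos)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  cuts <- sort(unique(ranking$weight), decreasing = TRUE)
  tpr <- c(0, vapply(cuts, function(c) sum(pos & ranking$weight >= c) / npos,
                     numeric(1)))
  fpr <- c(0, vapply(cuts, function(c) sum(!pos & ranking$weight >= c) / nneg,
                     numeric(1)))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Mutual predictability of one driver-DRG pair
#'
#' `auc_driver` measures how well the driver's weighted neighborhood recovers
#' the full DRG set; `auc_drg` how well the DRG's neighborhood recovers the
#' full driver set; the score is the geometric mean `sqrt(a1 * a2)`.  The
#' partner gene is kept inside its positive set unless `leave_one_out` is
#' set.  Undefined when either directional AUC is undefined.
#'
#' @param net A [functional_network()].
#' @param driver,drg The pair of genes.
#' @param driver_set,drg_set Full category sets; `driver` must be in
#'   `driver_set`, `drg` in `drg_set`, and both in the network.
#' @param category Optional category label carried into the result.
#' @param leave_one_out Drop the partner gene from the positive set when
#'   scoring its mate (default `FALSE`).
#' @return A one-row data frame (`driver`, `drg`, `category`, `auc_driver`,
#'   `auc_drg`, `score`), or `NULL` when the score is undefined.
#' @export
mutual_predictability <- function(net, driver, drg, driver_set, drg_set,
                                  category = NA_character_,
                                  leave_one_out = FALSE) {
  if (!driver %in% driver_set) stop("driver not in driver_set: ", driver,
                                    call. = FALSE)
  if (!drg %in% drg_set) stop("drg not in drg_set: ", drg, call. = FALSE)
  if (!driver %in% net$nodes) stop("gene not in network: ", driver,
                                   call. = FALSE)
  if (!drg %in% net$nodes) stop("gene not in network: ", drg, call. = FALSE)
  pos_drg <- if (leave_one_out) setdiff(drg_set, drg) else drg_set
  pos_driver <- if (leave_one_out) setdiff(driver_set, driver) else driver_set
  a1 <- auc_recovery(neighbor_ranking(net, driver), pos_drg)
  a2 <- auc_recovery(neighbor_ranking(net, drg), pos_driver)
  if (is.na(a1) || is.na(a2)) return(NULL)
  data.frame(driver = driver, drg = drg, category = category,
             auc_driver = a1, auc_drg = a2, score = sqrt(a1 * a2),
             stringsAsFactors = FALSE)
}

#' Top-k driver-DRG pairs by mutual predictability
#'
#' Scores the full Cartesian product of one driver category against the DRG
#' set, drops undefined pairs, sorts by score descending (ties by
#' `auc_driver + auc_drg` descending, then driver id, then drg id) and
#' returns the first `k`.
#'
#' @param net A [functional_network()].
#' @param drivers A `driver_gene_set` (or character vector of driver genes).
#' @param drgs A [drg_annotation()] (or character vector of DRGs).
#' @param k Number of pairs to keep (default 100).
#' @param category Category label; defaults to the driver set's category.
#' @param leave_one_out Passed to [mutual_predictability()].
#' @return Data frame of ranked pairs with a `rank` column (possibly fewer
#'   than `k` rows; zero rows with a warning when either set is empty).
#' @export
top_pairs <- function(net, drivers, drgs, k = 100L, category = NULL,
                      leave_one_out = FALSE) {
  stopifnot(k >= 1L)
  driver_set <- if (inherits(drivers, "driver_gene_set")) drivers$genes else drivers
  drg_set <- if (inherits(drgs, "drg_annotation")) unique(drgs$gene) else drgs
  if (is.null(category)) {
    category <- if (inherits(drivers, "driver_gene_set")) drivers$category
                else NA_character_
  }
  empty <- data.frame(driver = character(), drg = character(),
                      category = character(), auc_driver = numeric(),
                      auc_drg = numeric(), score = numeric(),
                      rank = integer(), stringsAsFactors = FALSE)
  if (length(driver_set) == 0L || length(drg_set) == 0L) {
    warning("empty driver or DRG set; no pairs scored", call. = FALSE)
    return(empty)
  }
  driver_set <- intersect(driver_set, net$nodes)
  drg_set_net <- intersect(drg_set, net$nodes)
  if (length(driver_set) == 0L || length(drg_set_net) == 0L) {
    warning("no driver or DRG present in the network", call. = FALSE)
    return(empty)
  }
  net <- index_network(net)
  # directional AUCs depend only on the gene and the opposing set: compute
  # each once, then expand to the Cartesian product
  a_driver <- vapply(driver_set, function(d) {
    auc_recovery(neighbor_ranking(net, d), drg_set)
  }, numeric(1))
  a_drg <- vapply(drg_set_net, function(g) {
    auc_recovery(neighbor_ranking(net, g), driver_set)
  }, numeric(1))
  grid <- expand.grid(driver = driver_set, drg = drg_set_net,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (leave_one_out) {
    rows <- mapply(function(d, g) {
      mutual_predictability(net, d, g, driver_set, drg_set_net,
                            category = category, leave_one_out = TRUE)
    }, grid$driver, grid$drg, SIMPLIFY = FALSE)
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out)) out <- empty[, 1:6]
  } else {
    out <- data.frame(driver = grid$driver, drg = grid$drg,
                      category = category,
                      auc_driver = a_driver[grid$driver],
                      auc_drg = a_drg[grid$drg],
                      stringsAsFactors = FALSE)
    out$score <- sqrt(out$auc_driver * out$auc_drg)
    out <- out[!is.na(out$score), , drop = FALSE]
  }
  if (nrow(out) == 0L) {
    warning("no defined pairs (every candidate had an empty AUC class)",
            call. = FALSE)
    return(empty)
  }
  ord <- order(-out$score, -(out$auc_driver + out$auc_drg),
               out$driver, out$drg)
  out <- out[ord, , drop = FALSE][seq_len(min(k, nrow(out))), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
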