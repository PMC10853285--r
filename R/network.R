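#' Logistic-regression confirmation of one disease pair
#'
#' Within the pair sub-cohort of exposed patients (neither code before
#' follow-up start), regresses "D2 ever during follow-up" on "D1 ever during
#' follow-up", optionally adjusted for covariates (default sex and birth year
#' as a continuous term).  Returns the maximum-likelihood odds ratio and Wald
#' p-value.  A zero cell in the 2x2 exposure-outcome table (separation) makes
#' the pair non-estimable.
#'
#' @inheritParams pair_subcohort_counts
#' @param covariates character subset of c("sex", "birth_year"), or NULL.
#' @return list(code_i, code_j, or, p, estimable).
#' @export
pair_logistic_or <- function(cohort, registry, code_i, code_j,
                             covariates = c("sex", "birth_year")) {
  inc <- exposed_incidence(cohort, registry, c(code_i, code_j))
  sub <- !inc$prior[, 1L] & !inc$prior[, 2L]
  dat <- data.table(d1 = as.integer(inc$during[sub, 1L]),
                    d2 = as.integer(inc$during[sub, 2L]))
  if (length(covariates) > 0L) {
    per <- cohort[role == "exposed"][sub]
    if ("sex" %in% covariates) dat[, sex := per$sex]
    if ("birth_year" %in% covariates) dat[, birth_year := per$birth_year]
  }
  res <- list(code_i = code_i, code_j = code_j, or = NA_real_, p = NA_real_,
              estimable = FALSE)
  cells <- table(factor(dat$d1, 0:1), factor(dat$d2, 0:1))
  if (any(cells == 0L)) return(res)
  fml <- as.formula(paste("d2 ~", paste(c("d1", covariates), collapse = " + ")))
  fit <- tryCatch(glm(fml, data = dat, family = binomial()),
                  error = function(e) NULL)
  if (is.null(fit)) return(res)
  beta <- coef(fit)[["d1"]]
  se <- sqrt(diag(vcov(fit)))[["d1"]]
  if (!is.finite(beta) || !is.finite(se) || se > 50) return(res)
  list(code_i = code_i, code_j = code_j, or = exp(beta),
       p = 2 * pnorm(-abs(beta / se)), estimable = TRUE)
}

#' Confirm screened pairs by logistic regression
#'
#' Fits [pair_logistic_or()] for every retained pair from [screen_pairs()],
#' adjusts p-values across all tested pairs with Benjamini-Hochberg, and
#' flags confirmed edges (OR > 1, q < `alpha`).
#'
#' @inheritParams pair_logistic_or
#' @param pairs output of [screen_pairs()] (its retained rows are tested).
#' @param alpha FDR threshold.
#' @return data.table (code_i, code_j, or, p, q, estimable, confirmed).
#' @export
confirm_edges <- function(cohort, registry, pairs, alpha = 0.05,
                          covariates = c("sex", "birth_year")) {
  tested <- pairs[retained == TRUE]
  if (nrow(tested) == 0L)
    return(data.table(code_i = character(), code_j = character(),
                      or = numeric(), p = numeric(), q = numeric(),
                      estimable = logical(), confirmed = logical()))
  res <- rbindlist(lapply(seq_len(nrow(tested)), function(r)
    pair_logistic_or(cohort, registry, tested$code_i[r], tested$code_j[r],
                     covariates)))
  res[, q := bh_adjust(fifelse(estimable, p, NA_real_))]
  res[, confirmed := estimable & !is.na(q) & or > 1 & q < alpha]
  res[]
}

#' Build the comorbidity network
#'
#' Undirected graph whose nodes are codes incident to at least one confirmed
#' edge; edge weights are ln(OR), positive by construction since confirmed
#' edges have OR > 1.  `weighted = FALSE` gives unit weights.
#'
#' @param edges output of [confirm_edges()] (its confirmed rows are used).
#' @param weighted use ln(OR) edge weights.
#' @return an [igraph::graph] object.
#' @export
build_network <- function(edges, weighted = TRUE) {
  conf <- edges[confirmed == TRUE]
  if (nrow(conf) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  g <- igraph::graph_from_data_frame(
    conf[, .(from = code_i, to = code_j)], directed = FALSE)
  igraph::E(g)$weight <- if (weighted) log(conf$or) else rep(1, nrow(conf))
  g
}

#' Louvain partition of the comorbidity network
#'
#' Runs the Louvain community-detection algorithm `n_restarts` times with
#' seeds `seed .. seed + n_restarts - 1` and returns the partition with the
#' highest modularity (first maximum on ties), making the result
#' deterministic given (graph, seed, n_restarts).
#'
#' @param graph an undirected, possibly weighted [igraph::graph].
#' @param seed integer base seed.
#' @param n_restarts number of restarts.
#' @param resolution Louvain resolution parameter.
#' @return An object of class `module_partition`: list(membership = named
#'   integer vector code -> module id, modularity, seed, n_restarts).
#' @export
louvain_partition <- function(graph, seed = 1L, n_restarts = 20L,
                              resolution = 1) {
  if (igraph::vcount(graph) == 0L) stopf("graph is empty")
  best <- NULL
  best_mod <- -Inf
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    cl <- igraph::cluster_louvain(graph, resolution = resolution)
    mod <- igraph::modularity(cl)
    if (mod > best_mod + 1e-12) {
      best <- cl
      best_mod <- mod
    }
  }
  membership <- igraph::membership(best)
  structure(list(membership = setNames(as.integer(membership),
                                       names(membership)),
                 modularity = best_mod,
                 seed = seed, n_restarts = n_restarts),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d codes, %d modules, modularity %.4f\n",
              length(x$membership), length(unique(x$membership)),
              x$modularity))
  invisible(x)
}
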