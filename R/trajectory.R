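#' Temporal direction test for one disease pair
#'
#' Among pair sub-cohort patients with both codes first diagnosed during
#' follow-up, compares the two first-diagnosis dates.  Same-day pairs carry
#' no orientation information and are counted as ties, excluded from the
#' test.  The p-value is the exact two-sided binomial probability of
#' `n_forward` out of `n_forward + n_backward` under a fair coin, capped at
#' 1.  Orientation itself is assigned by [test_directions()] after FDR
#' adjustment across pairs.
#'
#' @inheritParams pair_subcohort_counts
#' @return list(code_i, code_j, n_forward, n_backward, n_tied, p,
#'   majority) where majority is "i->j", "j->i" or "none".
#' @export
direction_test <- function(cohort, registry, code_i, code_j) {
  inc <- exposed_incidence(cohort, registry, c(code_i, code_j))
  sub <- !inc$prior[, 1L] & !inc$prior[, 2L]
  both <- sub & inc$during[, 1L] & inc$during[, 2L]
  di <- inc$first_date[both, 1L]
  dj <- inc$first_date[both, 2L]
  n_forward <- sum(di < dj)
  n_backward <- sum(di > dj)
  n_tied <- sum(di == dj)
  n <- n_forward + n_backward
  p <- if (n == 0L) 1 else
    min(1, binom.test(n_forward, n, p = 0.5)$p.value)
  majority <- if (n_forward > n_backward) "i->j" else
    if (n_backward > n_forward) "j->i" else "none"
  list(code_i = code_i, code_j = code_j, n_forward = n_forward,
       n_backward = n_backward, n_tied = n_tied, p = p, majority = majority)
}

#' Direction tests with FDR-controlled orientation assignment
#'
#' Runs [direction_test()] for every retained pair, adjusts the binomial
#' p-values across pairs with Benjamini-Hochberg, and assigns the majority
#' orientation to pairs with q < `alpha` (direction "none" otherwise).
#' Setting `alpha = NULL` assigns the majority orientation whenever the
#' counts are not tied, without a significance gate.
#'
#' @inheritParams confirm_edges
#' @param alpha FDR threshold for orientation, or NULL to orient every
#'   untied pair.
#' @return data.table (code_i, code_j, n_forward, n_backward, n_tied, p, q,
#'   direction).
#' @export
test_directions <- function(cohort, registry, pairs, alpha = 0.05) {
  tested <- pairs[retained == TRUE]
  if (nrow(tested) == 0L)
    return(data.table(code_i = character(), code_j = character(),
                      n_forward = integer(), n_backward = integer(),
                      n_tied = integer(), p = numeric(), q = numeric(),
                      direction = character()))
  res <- rbindlist(lapply(seq_len(nrow(tested)), function(r)
    direction_test(cohort, registry, tested$code_i[r], tested$code_j[r])))
  res[, q := bh_adjust(p)]
  oriented <- if (is.null(alpha)) res$majority != "none" else
    !is.na(res$q) & res$q < alpha & res$majority != "none"
  res[, direction := fifelse(oriented, majority, "none")]
  res[, majority := NULL]
  res[]
}

#' Nested case-control set for a directed pair
#'
#' Within the pair sub-cohort (exposed patients with neither code before
#' follow-up start), each patient first diagnosed with the downstream code
#' D2 during follow-up becomes a case at that date.  At most `n_controls`
#' controls are matched by sex and birth year using incidence-density
#' sampling: eligible controls are sub-cohort members in follow-up at the
#' case date and still D2-free on that date (a later case may serve as an
#' earlier control).  Exposure for everyone in a set is a first D1 diagnosis
#' strictly before the case's D2 date.  Cases with no eligible control are
#' dropped and counted in the `n_unmatched` attribute.
#'
#' @inheritParams pair_subcohort_counts
#' @param code_from upstream code D1 (the exposure of the nested analysis).
#' @param code_to downstream code D2 (the outcome).
#' @param n_controls maximum controls per case (default 2).
#' @param seed sampling seed.
#' @return data.table (set_id, person_id, case, exposed, sex, birth_year).
#' @export
nested_case_control <- function(cohort, registry, code_from, code_to,
                                n_controls = 2L, seed = 1L) {
  n_controls <- assert_count(n_controls, "n_controls", min = 1L)
  set.seed(seed)
  inc <- exposed_incidence(cohort, registry, c(code_from, code_to))
  sub <- which(!inc$prior[, 1L] & !inc$prior[, 2L])
  per <- cohort[role == "exposed"][sub]
  d1_date <- inc$first_date[sub, 1L]
  d1_date[!inc$during[sub, 1L]] <- NA_integer_   # only in-window D1 counts
  d2_date <- inc$first_date[sub, 2L]
  d2_date[!inc$during[sub, 2L]] <- NA_integer_
  fu_start <- as.integer(per$fu_start)
  fu_end <- as.integer(per$fu_end)
  n_cases <- sum(!is.na(d2_date))
  out <- vector("list", n_cases)
  n_unmatched <- 0L
  sid <- 0L
  # candidate scans are confined to the (sex, birth year) matching stratum
  groups <- split(seq_len(nrow(per)), list(per$sex, per$birth_year),
                  drop = TRUE)
  groups <- groups[order(names(groups))]
  for (g in groups) {
    g_d2 <- d2_date[g]
    g_cases <- g[!is.na(g_d2)]
    g_cases <- g_cases[order(d2_date[g_cases], per$person_id[g_cases])]
    for (cs in g_cases) {
      d <- d2_date[cs]
      elig <- g[fu_start[g] <= d & fu_end[g] >= d &
                  (is.na(g_d2) | g_d2 > d)]
      elig <- elig[elig != cs]
      if (length(elig) == 0L) {
        n_unmatched <- n_unmatched + 1L
        next
      }
      k <- min(n_controls, length(elig))
      ctrl <- elig[sample.int(length(elig), k)]
      sid <- sid + 1L
      members <- c(cs, ctrl)
      out[[sid]] <- data.table(
        set_id = sid,
        person_id = per$person_id[members],
        case = c(1L, rep(0L, k)),
        exposed = as.integer(!is.na(d1_date[members]) & d1_date[members] < d),
        sex = per$sex[cs], birth_year = per$birth_year[cs])
    }
  }
  res <- if (sid > 0L) rbindlist(out[seq_len(sid)]) else
    data.table(set_id = integer(), person_id = integer(), case = integer(),
               exposed = integer(), sex = character(), birth_year = integer())
  setattr(res, "n_unmatched", n_unmatched)
  res[]
}

#' Conditional logistic regression on a nested case-control set
#'
#' Conditional maximum likelihood on the matched sets (via
#' [survival::clogit()]), optionally adjusted for covariate columns present
#' in `sets`.  Non-estimable when no set is informative (exposure constant
#' within every set).  On 1:1 sets without covariates the estimate equals
#' the classic discordant-pair ratio.
#'
#' @param sets output of [nested_case_control()].
#' @param covariates character vector of column names in `sets`, or NULL.
#' @return list(or, p, n_sets, n_informative, estimable).
#' @export
conditional_logistic_or <- function(sets, covariates = NULL) {
  res <- list(or = NA_real_, p = NA_real_,
              n_sets = length(unique(sets$set_id)),
              n_informative = 0L, estimable = FALSE)
  if (nrow(sets) == 0L) return(res)
  info <- sets[, .(informative = length(unique(exposed)) > 1L), by = set_id]
  res$n_informative <- sum(info$informative)
  if (res$n_informative == 0L) return(res)
  fml <- as.formula(paste("case ~",
                          paste(c("exposed", covariates), collapse = " + "),
                          "+ strata(set_id)"))
  fit <- tryCatch(survival::clogit(fml, data = sets),
                  error = function(e) NULL)
  if (is.null(fit)) return(res)
  beta <- coef(fit)[["exposed"]]
  se <- sqrt(diag(vcov(fit)))[["exposed"]]
  if (!is.finite(beta) || !is.finite(se) || se > 50) return(res)
  res$or <- exp(beta)
  res$p <- 2 * pnorm(-abs(beta / se))
  res$estimable <- TRUE
  res
}

#' Confirm directed pairs and assemble trajectory edges
#'
#' For every oriented pair from [test_directions()], builds the nested
#' case-control set with the upstream code as exposure and the downstream
#' code as outcome, fits the conditional logistic model, adjusts p-values
#' across directed pairs with Benjamini-Hochberg, and retains edges with
#' OR > 1 and q < `alpha`.
#'
#' @inheritParams nested_case_control
#' @param directions output of [test_directions()].
#' @param alpha FDR threshold.
#' @param covariates covariates for the conditional model (must be columns
#'   of the nested sets; sex and birth year are constant within a matched
#'   set, so the default is none).
#' @return data.table (from, to, or, p, q, n_sets, n_informative, estimable,
#'   retained).
#' @export
trajectory_edges <- function(cohort, registry, directions, n_controls = 2L,
                             seed = 1L, alpha = 0.05, covariates = NULL) {
  oriented <- directions[direction != "none"]
  empty <- data.table(from = character(), to = character(), or = numeric(),
                      p = numeric(), q = numeric(), n_sets = integer(),
                      n_informative = integer(), estimable = logical(),
                      retained = logical())
  if (nrow(oriented) == 0L) return(empty[])
  res <- rbindlist(lapply(seq_len(nrow(oriented)), function(r) {
    fwd <- oriented$direction[r] == "i->j"
    from <- if (fwd) oriented$code_i[r] else oriented$code_j[r]
    to <- if (fwd) oriented$code_j[r] else oriented$code_i[r]
    sets <- nested_case_control(cohort, registry, from, to, n_controls,
                                seed = seed + r - 1L)
    fit <- conditional_logistic_or(sets, covariates)
    data.table(from = from, to = to, or = fit$or, p = fit$p,
               n_sets = fit$n_sets, n_informative = fit$n_informative,
               estimable = fit$estimable)
  }))
  res[, q := bh_adjust(fifelse(estimable, p, NA_real_))]
  res[, retained := estimable & !is.na(q) & or > 1 & q < alpha]
  setcolorder(res, names(empty))
  res[]
}

#' Assemble the disease trajectory graph and its first layer
#'
#' Builds the directed graph of retained trajectory edges.  The first layer
#' D1 is the set of nodes with in-degree zero: conditions with no upstream
#' disease within the trajectory, i.e. those listed immediately after the
#' index diagnosis.  Cycles are detected and reported in `cyclic_nodes`
#' (nodes of non-trivial strongly connected components), never silently
#' broken; by the in-degree rule such nodes cannot enter D1.
#'
#' @param edges output of [trajectory_edges()] (its retained rows are used).
#' @return An object of class `trajectory_graph`: list(graph, edges, d1,
#'   cyclic_nodes).
#' @export
build_trajectory <- function(edges) {
  ret <- edges[retained == TRUE]
  if (nrow(ret) == 0L) {
    g <- igraph::make_empty_graph(0, directed = TRUE)
    return(structure(list(graph = g, edges = ret, d1 = character(),
                          cyclic_nodes = character()),
                     class = "trajectory_graph"))
  }
  g <- igraph::graph_from_data_frame(ret[, .(from, to)], directed = TRUE)
  indeg <- igraph::degree(g, mode = "in")
  d1 <- sort(names(indeg)[indeg == 0L])
  comp <- igraph::components(g, mode = "strong")
  cyc_comp <- which(comp$csize > 1L)
  cyclic <- sort(names(comp$membership)[comp$membership %in% cyc_comp])
  structure(list(graph = g, edges = ret, d1 = d1, cyclic_nodes = cyclic),
            class = "trajectory_graph")
}

#' @export
print.trajectory_graph <- function(x, ...) {
  cat(sprintf("<trajectory_graph> %d nodes, %d edges, D1 = {%s}%s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              paste(x$d1, collapse = ", "),
              if (length(x$cyclic_nodes))
                sprintf(" [cycles: %s]", paste(x$cyclic_nodes, collapse = ", "))
              else ""))
  invisible(x)
}
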