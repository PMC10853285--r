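#' Merge the trajectory and module views into disease clusters
#'
#' A disease cluster is rooted in the trajectory's first layer: D1 roots are
#' grouped by their comorbidity-module id, and each module with at least one
#' root yields one cluster whose members are those roots plus every
#' trajectory descendant of any of them that carries the same module id.
#' Reachability is computed on the full retained directed graph, so paths
#' may pass through out-of-module nodes (`in_module_paths = TRUE` restricts
#' paths to the module instead); membership is always filtered to the
#' module.  Trajectory codes absent from the partition are skipped and
#' reported in the `skipped_codes` attribute.  Modules without a D1 root
#' yield no cluster.
#'
#' @param trajectory a `trajectory_graph` from [build_trajectory()].
#' @param partition a `module_partition` from [louvain_partition()].
#' @param in_module_paths restrict descendant paths to same-module nodes.
#' @return An object of class `disease_clusters`: list of clusters, each
#'   list(cluster_id, module_id, roots, members, size); members of distinct
#'   clusters are disjoint.
#' @export
merge_clusters <- function(trajectory, partition, in_module_paths = FALSE) {
  stopifnot(inherits(trajectory, "trajectory_graph"),
            inherits(partition, "module_partition"))
  mem <- partition$membership
  g <- trajectory$graph
  nodes <- if (igraph::vcount(g) > 0L) igraph::V(g)$name else character()
  skipped <- sort(setdiff(c(trajectory$d1, nodes), names(mem)))
  roots <- intersect(trajectory$d1, names(mem))
  clusters <- list()
  for (m in sort(unique(mem[roots]))) {
    m_roots <- sort(roots[mem[roots] == m])
    gm <- g
    if (in_module_paths) {
      keep <- intersect(nodes, names(mem)[mem == m])
      gm <- igraph::induced_subgraph(g, keep)
    }
    desc <- unique(unlist(lapply(intersect(m_roots, igraph::V(gm)$name),
                                 function(r)
      names(igraph::subcomponent(gm, r, mode = "out")))))
    members <- sort(union(m_roots,
                          desc[desc %in% names(mem) & mem[desc] == m]))
    clusters[[length(clusters) + 1L]] <- list(
      cluster_id = sprintf("cluster_%d", length(clusters) + 1L),
      module_id = as.integer(m), roots = m_roots, members = members,
      size = length(members))
  }
  structure(clusters, skipped_codes = skipped, class = "disease_clusters")
}

#' Network-only disease clusters (validation mode)
#'
#' When temporal data are too incomplete for trajectory analysis (the
#' validation-register situation), clusters are the comorbidity modules
#' themselves, with empty root sets, restricted to `codes` when given.
#'
#' @param partition a `module_partition`.
#' @param codes optional code universe (e.g. the validation PheWAS-selected
#'   codes); NULL keeps every partitioned code.
#' @return a `disease_clusters` object with empty `roots`.
#' @export
network_only_clusters <- function(partition, codes = NULL) {
  stopifnot(inherits(partition, "module_partition"))
  mem <- partition$membership
  if (!is.null(codes)) mem <- mem[names(mem) %in% codes]
  clusters <- list()
  for (m in sort(unique(mem))) {
    members <- sort(names(mem)[mem == m])
    clusters[[length(clusters) + 1L]] <- list(
      cluster_id = sprintf("cluster_%d", length(clusters) + 1L),
      module_id = as.integer(m), roots = character(), members = members,
      size = length(members))
  }
  structure(clusters, skipped_codes = character(), class = "disease_clusters")
}

#' @export
print.disease_clusters <- function(x, ...) {
  cat(sprintf("<disease_clusters> %d cluster(s)\n", length(x)))
  for (cl in x)
    cat(sprintf("  %s (module %d, %d members): %s\n", cl$cluster_id,
                cl$module_id, cl$size, paste(cl$members, collapse = ", ")))
  invisible(x)
}

#' Per-patient cluster susceptibility scores
#'
#' For each exposed cohort member and each cluster, the score is the number
#' of distinct cluster-member codes with at least one diagnosis during the
#' person's follow-up; repeat diagnoses of the same code do not add.
#'
#' @inheritParams prevalence_filter
#' @param clusters a `disease_clusters` object.
#' @return data.table (person_id, cluster_id, score), one row per exposed
#'   patient and cluster.
#' @export
susceptibility_scores <- function(registry, cohort, clusters) {
  stopifnot(inherits(clusters, "disease_clusters"))
  if (length(clusters) == 0L)
    return(data.table(person_id = integer(), cluster_id = character(),
                      score = integer()))
  all_members <- unique(unlist(lapply(clusters, `[[`, "members")))
  inc <- exposed_incidence(cohort, registry, all_members)
  rbindlist(lapply(clusters, function(cl) {
    cols <- match(cl$members, all_members)
    data.table(person_id = inc$persons$person_id,
               cluster_id = cl$cluster_id,
               score = as.integer(rowSums(inc$during[, cols, drop = FALSE])))
  }))
}

#' Export susceptibility scores in a phenotype layout
#'
#' Writes a plink-style phenotype table (FID, IID, one column per cluster)
#' for downstream genetic association tooling.
#'
#' @param scores output of [susceptibility_scores()].
#' @param path output file (tab-delimited).
#' @return the wide table, invisibly.
#' @export
write_score_phenotypes <- function(scores, path) {
  wide <- dcast(scores, person_id ~ cluster_id, value.var = "score")
  out <- data.table(FID = wide$person_id, IID = wide$person_id)
  out <- cbind(out, wide[, !"person_id"])
  fwrite(out, path, sep = "\t")
  invisible(out)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Recovery report against planted ground truth
#'
#' Greedy best matching between planted and estimated clusters on the
#' Jaccard index of their member sets: the highest-Jaccard (planted,
#' estimated) pair is matched first, both are removed, and so on; planted
#' clusters left without a partner score zero.  Precision and recall are
#' member-level for the matched pair.
#'
#' @param clusters a `disease_clusters` object (the estimate).
#' @param truth the `membership` element of [ground_truth()] (named list of
#'   member-code vectors).
#' @return data.table (planted, matched, jaccard, precision, recall).
#' @export
cluster_recovery_report <- function(clusters, truth) {
  est <- lapply(clusters, `[[`, "members")
  names(est) <- vapply(clusters, `[[`, character(1), "cluster_id")
  res <- data.table(planted = names(truth), matched = NA_character_,
                    jaccard = 0, precision = 0, recall = 0)
  if (length(est) == 0L || length(truth) == 0L) return(res[])
  jmat <- outer(seq_along(truth), seq_along(est),
                Vectorize(function(i, j) jaccard(truth[[i]], est[[j]])))
  repeat {
    if (all(is.na(jmat)) || max(jmat, na.rm = TRUE) == 0) break
    ix <- which(jmat == max(jmat, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    ti <- ix[[1L]]; ei <- ix[[2L]]
    inter <- length(intersect(truth[[ti]], est[[ei]]))
    res[ti, `:=`(matched = names(est)[ei], jaccard = jmat[ti, ei],
                 precision = inter / length(est[[ei]]),
                 recall = inter / length(truth[[ti]]))]
    jmat[ti, ] <- NA_real_
    jmat[, ei] <- NA_real_
  }
  res[]
}

#' Overlap report between two cluster sets
#'
#' Best-match Jaccard overlap of each cluster in `x` against the clusters
#' in `y` (e.g. exploration clusters against validation-mode modules).
#' Matching is greedy as in [cluster_recovery_report()], except that a
#' cluster in `y` may absorb several clusters of `x` when
#' `allow_merging = TRUE`, mirroring the situation where two exploration
#' clusters replicate as a single merged validation module.
#'
#' @param x,y `disease_clusters` objects.
#' @param allow_merging may several `x` clusters map to one `y` cluster.
#' @return data.table (cluster, matched, jaccard).
#' @export
cluster_overlap_report <- function(x, y, allow_merging = TRUE) {
  xs <- lapply(x, `[[`, "members")
  names(xs) <- vapply(x, `[[`, character(1), "cluster_id")
  ys <- lapply(y, `[[`, "members")
  names(ys) <- vapply(y, `[[`, character(1), "cluster_id")
  res <- data.table(cluster = names(xs), matched = NA_character_, jaccard = 0)
  if (length(ys) == 0L) return(res[])
  for (i in seq_along(xs)) {
    j <- vapply(ys, jaccard, numeric(1), a = xs[[i]])
    best <- which.max(j)
    res[i, `:=`(matched = names(ys)[best], jaccard = j[best])]
  }
  if (!allow_merging) {
    # resolve collisions greedily by Jaccard
    ord <- order(-res$jaccard)
    used <- character()
    for (i in ord) {
      if (res$matched[i] %in% used) {
        remaining <- setdiff(names(ys), used)
        if (length(remaining) == 0L) {
          res[i, `:=`(matched = NA_character_, jaccard = 0)]
          next
        }
        j <- vapply(ys[remaining], jaccard, numeric(1), a = xs[[i]])
        res[i, `:=`(matched = remaining[which.max(j)], jaccard = max(j))]
      }
      used <- c(used, res$matched[i])
    }
  }
  res[]
}
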