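# hand-built module partition and trajectory objects for merge tests
mk_partition <- function(membership) {
  structure(list(membership = membership, modularity = 0.5,
                 seed = 1L, n_restarts = 1L),
            class = "module_partition")
}

mk_trajectory <- function(from, to) {
  build_trajectory(data.table(from = from, to = to, or = 2, retained = TRUE))
}

test_that("cluster merge groups D1 roots by module and filters descendants", {
  # roots {A, B}; modules A,C,D -> 1 and B,E -> 2; edges A->C, A->E, B->E,
  # C->D: expected clusters {A,C,D} and {B,E}
  part <- mk_partition(c(A = 1L, C = 1L, D = 1L, B = 2L, E = 2L))
  traj <- mk_trajectory(c("A", "A", "B", "C"), c("C", "E", "E", "D"))
  expect_equal(sort(traj$d1), c("A", "B"))
  cl <- merge_clusters(traj, part)
  expect_length(cl, 2L)
  expect_equal(cl[[1]]$members, c("A", "C", "D"))
  expect_equal(cl[[1]]$roots, "A")
  expect_equal(cl[[2]]$members, c("B", "E"))
  # module purity and disjointness
  for (c1 in cl)
    expect_length(unique(part$membership[c1$members]), 1L)
  expect_length(intersect(cl[[1]]$members, cl[[2]]$members), 0L)
})

test_that("descendant paths may pass through out-of-module nodes", {
  # A -> X -> D with X in another module: D still joins A's cluster because
  # membership, not the path, is filtered by module
  part <- mk_partition(c(A = 1L, D = 1L, X = 2L))
  traj <- mk_trajectory(c("A", "X"), c("X", "D"))
  cl <- merge_clusters(traj, part)
  m1 <- cl[[which(vapply(cl, `[[`, integer(1), "module_id") == 1L)]]
  expect_equal(m1$members, c("A", "D"))
  # strict in-module-path mode drops the relayed descendant
  cl2 <- merge_clusters(traj, part, in_module_paths = TRUE)
  m1s <- cl2[[which(vapply(cl2, `[[`, integer(1), "module_id") == 1L)]]
  expect_equal(m1s$members, "A")
})

test_that("rootless modules yield no cluster; same-module roots merge", {
  part <- mk_partition(c(A = 1L, B = 1L, C = 2L))
  # no edges at all: every root is a singleton, same-module roots merge
  traj <- build_trajectory(data.table(from = character(), to = character(),
                                      or = numeric(), retained = logical()))
  traj$d1 <- c("A", "B")   # D1 supplied without edges
  cl <- merge_clusters(traj, part)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$members, c("A", "B"))
  expect_equal(cl[[1]]$roots, c("A", "B"))
  # codes missing from the partition are skipped but reported
  traj2 <- mk_trajectory("A", "ZZ")
  cl2 <- merge_clusters(traj2, part)
  expect_true("ZZ" %in% attr(cl2, "skipped_codes"))
})

test_that("merge result ignores the ordering of the edge rows", {
  part <- mk_partition(c(A = 1L, C = 1L, D = 1L, B = 2L, E = 2L))
  ed <- data.table(from = c("A", "A", "B", "C"), to = c("C", "E", "E", "D"),
                   or = 2, retained = TRUE)
  cl1 <- merge_clusters(build_trajectory(ed), part)
  cl2 <- merge_clusters(build_trajectory(ed[c(4, 2, 1, 3)]), part)
  expect_equal(lapply(cl1, `[[`, "members"), lapply(cl2, `[[`, "members"))
})

test_that("network-only clusters mirror the modules with empty roots", {
  part <- mk_partition(c(A = 1L, B = 1L, C = 2L, D = 3L))
  cl <- network_only_clusters(part)
  expect_length(cl, 3L)
  expect_true(all(vapply(cl, function(x) length(x$roots) == 0L, logical(1))))
  expect_equal(cl[[1]]$members, c("A", "B"))
  # restriction to a code universe
  cl2 <- network_only_clusters(part, codes = c("A", "C", "D"))
  expect_equal(cl2[[1]]$members, "A")
})

test_that("cluster overlap reports merged replications", {
  exploration <- structure(list(
    list(cluster_id = "cluster_1", module_id = 1L, roots = "A",
         members = c("A", "B"), size = 2L),
    list(cluster_id = "cluster_2", module_id = 2L, roots = "C",
         members = "C", size = 1L)), class = "disease_clusters")
  validation <- network_only_clusters(mk_partition(c(A = 1L, B = 1L, C = 1L)))
  ov <- cluster_overlap_report(exploration, validation)
  # both exploration clusters map to the single merged validation module
  expect_equal(ov$matched, c("cluster_1", "cluster_1"))
  expect_equal(ov$jaccard, c(2 / 3, 1 / 3))
  # identical membership: Jaccard 1
  ov2 <- cluster_overlap_report(exploration, exploration)
  expect_equal(ov2$jaccard, c(1, 1))
})

test_that("susceptibility scores count distinct member codes in follow-up", {
  patterns <- list(
    list(d1 = "during", d2 = "during"),   # two members
    list(d1 = "during"),                  # one member
    list(),                               # none
    list(d1 = "prior"))                   # outside follow-up: not counted
  reg <- pattern_registry(patterns)
  # a repeat diagnosis of the same code must not add to the score
  reg$diagnoses <- rbind(reg$diagnoses,
                         data.table(person_id = 1L, code = "D10",
                                    date = as.IDate("2007-06-01")))
  coh <- all_exposed_cohort(reg)
  clusters <- structure(list(
    list(cluster_id = "cluster_1", module_id = 1L, roots = "D10",
         members = c("D10", "D20", "D99"), size = 3L)),
    class = "disease_clusters")
  sc <- susceptibility_scores(reg, coh, clusters)
  expect_equal(nrow(sc), 4L)
  expect_equal(sc[order(person_id), score], c(2L, 1L, 0L, 0L))
  expect_true(all(sc$score <= 3L))
})

test_that("score phenotypes export in FID/IID layout", {
  sc <- data.table(person_id = c(1L, 1L, 2L, 2L),
                   cluster_id = rep(c("cluster_1", "cluster_2"), 2),
                   score = c(2L, 0L, 1L, 3L))
  path <- withr::local_tempfile(fileext = ".tsv")
  wide <- write_score_phenotypes(sc, path)
  expect_equal(names(wide), c("FID", "IID", "cluster_1", "cluster_2"))
  back <- fread(path)
  expect_equal(back$cluster_2, c(0L, 3L))
  expect_equal(back$FID, back$IID)
})

test_that("recovery report computes greedy best-match Jaccard", {
  est <- structure(list(
    list(cluster_id = "cluster_1", module_id = 1L, roots = "A",
         members = c("A", "B", "C"), size = 3L)), class = "disease_clusters")
  truth <- list(planted_1 = c("A", "B", "C", "D"))
  rep1 <- cluster_recovery_report(est, truth)
  expect_equal(rep1$jaccard, 0.75)
  expect_equal(rep1$precision, 1)
  expect_equal(rep1$recall, 0.75)
  # perfect and disjoint estimates
  truth2 <- list(planted_1 = c("A", "B", "C"))
  expect_equal(cluster_recovery_report(est, truth2)$jaccard, 1)
  truth3 <- list(planted_1 = c("X", "Y"))
  expect_equal(cluster_recovery_report(est, truth3)$jaccard, 0)
})
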