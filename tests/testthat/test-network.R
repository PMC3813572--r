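test_that("node degrees count edges exactly", {
  labs <- paste0("ch", 1:5)
  empty <- adjacency_from_matrix(matrix(FALSE, 5, 5), labs)
  expect_true(all(node_degrees(empty)$out_degree == 0))
  expect_true(all(node_degrees(empty)$in_degree == 0))

  full <- matrix(TRUE, 5, 5); diag(full) <- FALSE
  deg <- node_degrees(adjacency_from_matrix(full, labs))
  expect_true(all(deg$out_degree == 4))
  expect_true(all(deg$in_degree == 4))

  # star 1 -> {2..5}: matrix is target x source
  star <- matrix(FALSE, 5, 5); star[2:5, 1] <- TRUE
  deg <- node_degrees(adjacency_from_matrix(star, labs))
  expect_equal(deg$out_degree, c(4, 0, 0, 0, 0))
  expect_equal(deg$in_degree, c(0, 1, 1, 1, 1))
  expect_equal(sum(deg$out_degree), sum(deg$in_degree))
})

test_that("degrees agree with the igraph reference on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(61)
  labs <- paste0("ch", 1:6)
  for (rep in 1:3) {
    m <- matrix(runif(36) < 0.3, 6, 6); diag(m) <- FALSE
    deg <- node_degrees(adjacency_from_matrix(m, labs))
    g <- igraph::graph_from_adjacency_matrix(t(m))  # igraph: row = source
    expect_equal(deg$out_degree,
                 unname(igraph::degree(g, mode = "out")))
    expect_equal(deg$in_degree,
                 unname(igraph::degree(g, mode = "in")))
  }
})

test_that("edge classification is exact and conserves the truth count", {
  labs <- paste0("ch", 1:4)
  truth <- ground_truth(data.frame(source = c("ch1", "ch2"),
                                   target = c("ch2", "ch3"),
                                   delay = c(1L, 2L), gain = 1), labs)
  m <- matrix(FALSE, 4, 4, dimnames = list(labs, labs))
  m["ch2", "ch1"] <- TRUE; m["ch3", "ch2"] <- TRUE
  cls <- classify_edges(adjacency_from_matrix(m, labs), truth)
  expect_equal(cls$n_false_positive, 0)
  expect_equal(cls$n_missed, 0)
  expect_equal(cls$n_true_detected, 2)

  # direction matters when respected, not otherwise
  m2 <- matrix(FALSE, 4, 4, dimnames = list(labs, labs))
  m2["ch1", "ch2"] <- TRUE   # reversed edge 2 -> 1
  cls_dir <- classify_edges(adjacency_from_matrix(m2, labs), truth, TRUE)
  expect_equal(cls_dir$n_true_detected, 0)
  expect_equal(cls_dir$n_false_positive, 1)
  cls_und <- classify_edges(adjacency_from_matrix(m2, labs), truth, FALSE)
  expect_equal(cls_und$n_true_detected, 1)

  # conservation over random adjacency / truth pairs
  set.seed(62)
  for (rep in 1:5) {
    m <- matrix(runif(16) < 0.4, 4, 4); diag(m) <- FALSE
    cls <- classify_edges(adjacency_from_matrix(m, labs), truth,
                          respect_direction = rep %% 2 == 0)
    expect_equal(cls$n_true_detected + cls$n_missed, cls$n_truth)
  }

  bad <- ground_truth(data.frame(source = "a", target = "b",
                                 delay = 1L, gain = 1), c("a", "b"))
  expect_error(classify_edges(adjacency_from_matrix(m, labs), bad),
               "label")
})

test_that("module partitions are validated", {
  expect_error(module_partition(list(c("a", "b"))), "name")
  expect_error(module_partition(list(M1 = c("a", "b"), M2 = c("b", "c"))),
               "overlap")
  expect_error(module_partition(list(M1 = c("a", "b"))), "2 modules")
  p <- default_partition_1020()
  expect_true("Pz" %in% p$modules$PL)
  expect_true("Pz" %in% default_partition_1020(pz = "PR")$modules$PR)
})

test_that("mixing matrix normalizes to one and counts blocks", {
  labs <- c("a1", "a2", "a3", "b1", "b2")
  part <- module_partition(list(A = c("a1", "a2", "a3"),
                                B = c("b1", "b2")))
  # uniform value c everywhere: E[k, l] proportional to the block pair count
  vals <- matrix(0.4, 5, 5, dimnames = list(labs, labs))
  ic <- structure(list(values = vals, band = c(1, 45), estimator = "DTF",
                       directed = TRUE, channel_labels = labs),
                  class = "integrated_conn")
  mm <- mixing_matrix(ic, part, threshold = 0.05)
  expect_lt(abs(sum(mm$e) - 1), 1e-9)
  counts <- matrix(c(6, 6, 6, 2), 2, byrow = TRUE)  # ordered pairs per block
  expect_equal(unname(mm$e), counts / sum(counts))

  # connections confined to module A
  vals2 <- matrix(0, 5, 5, dimnames = list(labs, labs))
  vals2[1:3, 1:3] <- 0.5
  ic2 <- ic; ic2$values <- vals2
  mm2 <- mixing_matrix(ic2, part, threshold = 0.05)
  expect_equal(unname(mm2$e), matrix(c(1, 0, 0, 0), 2, byrow = TRUE))

  # permutation equivariance under module reordering
  part_r <- module_partition(list(B = c("b1", "b2"),
                                  A = c("a1", "a2", "a3")))
  mm_r <- mixing_matrix(ic, part_r, threshold = 0.05)
  expect_equal(mm_r$e[c("A", "B"), c("A", "B")], mm$e)

  # mean variant divides by block pair counts
  mm_mean <- mixing_matrix(ic, part, threshold = 0.05, aggregate = "mean")
  expect_lt(abs(sum(mm_mean$e) - 1), 1e-9)
  expect_equal(unname(mm_mean$e), matrix(0.25, 2, 2))

  # singleton module: diagonal block has no pairs
  part_s <- module_partition(list(A = c("a1", "a2", "a3", "b1"),
                                  S = "b2"))
  expect_warning(mm_s <- mixing_matrix(ic, part_s), "single channel")
  expect_equal(unname(mm_s$e["S", "S"]), 0)

  expect_error(mixing_matrix(ic, part, threshold = 2), "threshold")
  expect_error(
    mixing_matrix(ic, module_partition(list(A = "a1", B = "a2"))),
    "cover")
})

test_that("assortativity report flags diagonal dominance", {
  part <- module_partition(list(A = c("a1", "a2"), B = c("b1", "b2")))
  mk <- function(E) {
    structure(list(e = E, normalized = TRUE, estimator = "DTF",
                   threshold = 0, aggregate = "sum", band = c(1, 45),
                   partition = part),
              class = "mixing_matrix")
  }
  Ediag <- diag(c(0.6, 0.4)); dimnames(Ediag) <- list(c("A", "B"),
                                                      c("A", "B"))
  rep_d <- assortativity_report(mk(Ediag))
  expect_true(attr(rep_d, "assortative"))
  expect_true(all(rep_d$ratio == 1e6))   # capped sentinel for zero off-diag

  Eunif <- matrix(0.25, 2, 2, dimnames = dimnames(Ediag))
  rep_u <- assortativity_report(mk(Eunif))
  expect_false(attr(rep_u, "assortative"))
  expect_equal(rep_u$ratio, c(1, 1))
})
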