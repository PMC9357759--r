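test_that("shipped layouts have the documented joint and edge counts", {
  s20 <- build_layout("synthetic20")
  expect_s3_class(s20, "skeleton_layout")
  expect_identical(s20$num_joints, 20L)
  expect_identical(nrow(s20$edges), 19L)

  expect_identical(build_layout("ntu25")$num_joints, 25L)
  expect_identical(build_layout("coco18")$num_joints, 18L)

  expect_error(build_layout("nope"), "unknown layout")
})

test_that("layout files are validated: bad indices, duplicates, disconnection", {
  # edge index out of range for a 20-joint skeleton
  expect_error(
    new_skeleton_layout("bad", paste0("j", 1:20),
                        rbind(cbind(1:18, 2:19), c(1L, 21L)),
                        matrix(seq_len(60), 20, 3), 1L),
    "out of range")
  expect_error(
    new_skeleton_layout("loop", c("a", "b"), rbind(c(1L, 1L)),
                        cbind(c(0, 1), 0, 0), 1L),
    "self-loop")
  expect_error(
    new_skeleton_layout("dup", c("a", "b", "c"),
                        rbind(c(1L, 2L), c(2L, 1L)),
                        cbind(c(0, 1, 2), 0, 0), 1L),
    "duplicate")
  # two components: edges (1,2) only on 3 joints
  expect_error(
    new_skeleton_layout("disc", c("a", "b", "c"),
                        rbind(c(1L, 2L), c(1L, 2L))[1, , drop = FALSE],
                        cbind(c(0, 1, 2), 0, 0), 1L),
    "connected tree")
  # a malformed layout file on disk
  f <- tempfile(fileext = ".yaml")
  writeLines("name: broken", f)
  expect_error(build_layout(f), "missing keys")
})

test_that("adjacency matrix has one symmetric pair per bone and zero diagonal", {
  expect_identical(
    adjacency_from_layout(new_skeleton_layout(
      "pair", c("a", "b"), rbind(c(1L, 2L)), cbind(c(0, 1), 0, 0), 1L)),
    matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b"))))

  a <- adjacency_from_layout(isolated1_layout())
  expect_identical(unname(a), matrix(0, 1, 1))

  s20 <- adjacency_from_layout(build_layout("synthetic20"))
  expect_identical(sum(s20 != 0), 38L)          # 2 entries per bone
  expect_identical(unname(s20), unname(t(s20)))
  expect_true(all(diag(s20) == 0))
})

test_that("adjacency normalization matches hand-computed values", {
  # isolated node: degree 1 with the self-loop
  expect_equal(normalize_adjacency(matrix(0, 1, 1))$normalized,
               matrix(1, 1, 1))
  # single edge: Lambda = diag(2, 2), all entries 0.5
  two <- normalize_adjacency(matrix(c(0, 1, 1, 0), 2))
  expect_equal(two$normalized, matrix(0.5, 2, 2))
  expect_equal(two$degree, c(2, 2))
  # 3-node path: Lambda = diag(2, 3, 2); oracle by direct matrix evaluation
  a <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  got <- normalize_adjacency(a)
  lam <- diag(1 / sqrt(c(2, 3, 2)))
  expect_equal(got$normalized, lam %*% (a + diag(3)) %*% lam)
  expect_equal(got$normalized[2, 2], 1 / 3)

  expect_error(normalize_adjacency(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(normalize_adjacency(matrix(c(1, 0, 0, 1), 2)), "diagonal")
})

test_that("centroid-distance partition labels match the three-subset rule", {
  lay <- collinear3_layout()
  norm <- normalize_adjacency(adjacency_from_layout(lay))$normalized
  part <- partition_spatial(lay, norm)
  lbl <- part$subset_labels
  # centroid is at x = 1 (joint 2): r = (1, 0, 1)
  expect_identical(diag(lbl), c(0L, 0L, 0L))      # self-pairs: stationary
  expect_identical(lbl[2, 1], 2L)                 # neighbor farther: centrifugal
  expect_identical(lbl[2, 3], 2L)
  expect_identical(lbl[1, 2], 1L)                 # neighbor closer: centripetal
  expect_identical(lbl[1, 3], -1L)                # not adjacent
  # subset matrices carry exactly the labelled entries
  expect_equal(Reduce(`+`, part$subsets), norm, ignore_attr = TRUE)
  expect_true(all(part$subsets[[1]][lbl != 0L] == 0))
})

test_that("an isolated joint partitions into the pure self-loop subset", {
  g <- graph_tensors(isolated1_layout())
  expect_equal(g$subsets[[1]], matrix(1, 1, 1))
  expect_equal(g$subsets[[2]], matrix(0, 1, 1))
  expect_equal(g$subsets[[3]], matrix(0, 1, 1))
})

test_that("partition invariants hold on all shipped and random layouts", {
  layouts <- c(lapply(c("synthetic20", "coco18", "ntu25"), build_layout),
               lapply(1:5, function(s) random_tree_layout(4L + 2L * s, s)))
  for (lay in layouts) {
    g <- graph_tensors(lay)
    # completeness: subsets sum to the normalized adjacency
    expect_lt(max(abs(Reduce(`+`, g$subsets) - g$normalized)), 1e-9)
    # disjoint support
    expect_lt(max(abs(g$subsets[[1]] * g$subsets[[2]])), 1e-12)
    expect_lt(max(abs(g$subsets[[1]] * g$subsets[[3]])), 1e-12)
    expect_lt(max(abs(g$subsets[[2]] * g$subsets[[3]])), 1e-12)
    # subset 0 support includes the full diagonal
    expect_true(all(diag(g$subsets[[1]]) > 0))
    # spectral bound of the symmetrically normalized operator
    ev <- eigen(g$normalized, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-9 & ev <= 1 + 1e-9))
  }
})

test_that("relabeling joints permutes graph tensors consistently", {
  lay <- build_layout("synthetic20")
  set.seed(42)
  perm <- sample.int(lay$num_joints)        # new index of old joint i
  inv <- order(perm)
  lay_p <- new_skeleton_layout(
    name = "permuted", joint_names = lay$joint_names[inv],
    edges = matrix(perm[lay$edges], ncol = 2L),
    template_pose = lay$template_pose[inv, ],
    center_joint = perm[lay$center_joint]
  )
  g <- graph_tensors(lay)
  gp <- graph_tensors(lay_p)
  p_mat <- diag(lay$num_joints)[inv, ]      # row i of P picks old joint inv[i]
  expect_equal(gp$normalized, p_mat %*% g$normalized %*% t(p_mat),
               ignore_attr = TRUE)
  expect_equal(gp$subset_labels, g$subset_labels[inv, inv])
  for (z in 1:3) {
    expect_equal(gp$subsets[[z]], p_mat %*% g$subsets[[z]] %*% t(p_mat),
                 ignore_attr = TRUE)
  }
})
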