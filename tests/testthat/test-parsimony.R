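# The maximum-parsimony engine: length computation, bounds, searches and
# ensemble statistics.

test_that("tree length handles forced-change and constant cases", {
  cells <- matrix(c("0", "0", "0", "0"), ncol = 1)
  rownames(cells) <- c("A", "B", "C", "D")
  cm <- character_matrix(cells, ordered = TRUE)
  # ((A,B),(C,D)) topology
  edges <- rbind(c(1L, 5L), c(2L, 5L), c(5L, 6L), c(3L, 6L), c(4L, 6L))
  expect_identical(tree_length(edges, cm), 0L)
  # ordered 3-state character 0,0,2,2 forces two steps across the middle
  cells2 <- matrix(c("0", "0", "2", "2"), ncol = 1,
                   dimnames = list(c("A", "B", "C", "D"), NULL))
  cm2 <- character_matrix(cells2, ordered = TRUE)
  expect_identical(tree_length(edges, cm2), 2L)
  # unordered: a single jump
  cm3 <- character_matrix(cells2, ordered = FALSE)
  expect_identical(tree_length(edges, cm3), 1L)
})

test_that("tree length equals brute-force ancestral enumeration", {
  set.seed(81)
  for (rep in 1:30) {
    g <- gen_character_matrix(
      evol_spec(6, 8, nstates = sample(2:3, 1),
                ordered = sample(c(TRUE, FALSE), 8, replace = TRUE),
                change_prob = 0.3, missing_rate = 0.1,
                polymorphism_rate = 0.15),
      seed = 8100 + rep)
    cm <- g$matrix
    edges <- random_edges(6)
    expect_identical(tree_length(edges, cm),
                     as.integer(brute_force_length(edges, cm$cells,
                                                   cm$ordered, cm$nstates,
                                                   6)),
                     label = paste("rep", rep))
  }
})

test_that("tree length is invariant to rerooting and character order", {
  set.seed(82)
  g <- gen_character_matrix(evol_spec(7, 12, change_prob = 0.3),
                            seed = 820)
  cm <- g$matrix
  edges <- random_edges(7)
  base <- tree_length(edges, cm)
  # any rotation of the edge rows and any relabeling of internal nodes
  perm <- sample(nrow(edges))
  expect_identical(tree_length(edges[perm, ], cm), base)
  # permuting characters leaves the total unchanged
  cmp <- cm
  jperm <- sample(ncol(cm$cells))
  cmp$cells <- cm$cells[, jperm]
  cmp$ordered <- cm$ordered[jperm]
  cmp$nstates <- cm$nstates[jperm]
  cmp$labels <- cm$labels[jperm]
  expect_identical(tree_length(edges, cmp), base)
  # phylo input agrees with edge-matrix input
  phy <- ape::read.tree(text = unguis:::canonical_newick(edges, cm$taxa,
                                                         cm$taxa[1]))
  expect_identical(tree_length(phy, cm), base)
})

test_that("ordered cost dominates unordered; binary characters coincide", {
  set.seed(83)
  for (rep in 1:50) {
    nch <- 6
    g <- gen_character_matrix(
      evol_spec(6, nch, nstates = 2, ordered = FALSE, change_prob = 0.4,
                missing_rate = 0.1, polymorphism_rate = 0.1),
      seed = 8300 + rep)
    cm_un <- g$matrix
    cm_or <- cm_un; cm_or$ordered <- rep(TRUE, nch)
    edges <- random_edges(6)
    # Wagner with |i-j| on binary states is exactly Fitch
    expect_identical(tree_length(edges, cm_or), tree_length(edges, cm_un))
  }
  for (rep in 1:30) {
    g <- gen_character_matrix(
      evol_spec(6, 6, nstates = 4, ordered = TRUE, change_prob = 0.4),
      seed = 8400 + rep)
    cm_or <- g$matrix
    cm_un <- cm_or; cm_un$ordered <- rep(FALSE, 6)
    edges <- random_edges(6)
    expect_gte(tree_length(edges, cm_or), tree_length(edges, cm_un))
  }
})

test_that("character bounds match closed forms and a star-tree oracle", {
  cells <- matrix(c("0", "0", "0", "1", "1"), ncol = 1,
                  dimnames = list(paste0("t", 1:5), NULL))
  cb <- char_bounds(character_matrix(cells, ordered = FALSE))
  expect_identical(cb$m, 1L)
  expect_identical(cb$g, 2L)
  cells2 <- matrix(c("0", "1", "2", "2"), ncol = 1,
                   dimnames = list(paste0("t", 1:4), NULL))
  cb2 <- char_bounds(character_matrix(cells2, ordered = TRUE))
  expect_identical(cb2$m, 2L)  # state range
  set.seed(84)
  for (rep in 1:40) {
    g <- gen_character_matrix(
      evol_spec(7, 5, nstates = sample(2:4, 1),
                ordered = sample(c(TRUE, FALSE), 5, replace = TRUE),
                change_prob = 0.4, missing_rate = 0.15,
                polymorphism_rate = 0.15),
      seed = 8500 + rep)
    cm <- g$matrix
    cb <- char_bounds(cm)
    for (j in seq_len(ncol(cm$cells)))
      expect_identical(cb$g[j],
                       as.integer(brute_force_star(cm$cells[, j],
                                                   cm$ordered[j],
                                                   cm$nstates[j])),
                       label = paste("rep", rep, "char", j))
    # m <= s <= g for a random tree
    s <- tree_length(random_edges(7), cm, per_character = TRUE)$steps
    expect_true(all(cb$m <= s & s <= cb$g))
  }
})

test_that("exhaustive search enumerates the double factorial", {
  g4 <- gen_character_matrix(evol_spec(4, 3, change_prob = 0.3),
                             seed = 85)
  r4 <- exhaustive_search(g4$matrix)
  expect_identical(r4$enumerated, 3L)
  g6 <- gen_character_matrix(evol_spec(6, 1, change_prob = 0.3),
                             seed = 86)
  expect_identical(exhaustive_search(g6$matrix)$enumerated, 105L)
  # refusal above the ceiling
  g7 <- gen_character_matrix(evol_spec(7, 1), seed = 87)
  expect_error(exhaustive_search(g7$matrix, ceiling = 6),
               "branch_and_bound")
})

test_that("branch and bound equals exhaustive search", {
  set.seed(88)
  for (rep in 1:10) {
    g <- gen_character_matrix(
      evol_spec(7, 10, change_prob = 0.25, missing_rate = 0.05,
                polymorphism_rate = 0.05),
      seed = 8800 + rep)
    re <- exhaustive_search(g$matrix)
    rb <- branch_and_bound(g$matrix)
    expect_identical(re$TL, rb$TL)
    expect_identical(vapply(mp_trees(re), ape::write.tree, ""),
                     vapply(mp_trees(rb), ape::write.tree, ""),
                     label = paste("rep", rep))
  }
  # a perfectly compatible (homoplasy-free) matrix yields exactly the
  # generating tree at CI = 1: one binary character per clade of
  # (t1,(t2,(t3,(t4,(t5,t6)))))
  cells <- cbind(c(0, 0, 0, 0, 1, 1),    # {t5,t6}
                 c(0, 0, 0, 1, 1, 1),    # {t4,t5,t6}
                 c(0, 0, 1, 1, 1, 1))    # {t3..t6}
  cells <- matrix(as.character(cells), 6,
                  dimnames = list(paste0("t", 1:6), NULL))
  cmp <- character_matrix(cells, ordered = TRUE, outgroup = "t1")
  rp <- branch_and_bound(cmp)
  expect_equal(tree_stats(rp)$CI, 1)
  expect_identical(ape::write.tree(mp_trees(rp)[[1]]),
                   "(t1,((((t5,t6),t4),t3),t2));")
})

test_that("ensemble statistics satisfy their identities", {
  set.seed(89)
  g <- gen_character_matrix(evol_spec(7, 15, change_prob = 0.3,
                                      polymorphism_rate = 0.1),
                            seed = 890)
  r <- branch_and_bound(g$matrix)
  st <- tree_stats(r)
  expect_identical(st$TL, as.integer(sum(r$steps)))
  expect_equal(st$HI, 1 - st$CI, tolerance = 1e-15)
  expect_equal(st$RC, st$CI * st$RI, tolerance = 1e-15)
  expect_true(st$CI >= 0 && st$CI <= 1)
  expect_true(st$RI >= 0 && st$RI <= 1)
  expect_true(sum(r$m) <= st$TL && st$TL <= sum(r$g))
  # adding a parsimony-uninformative (autapomorphic) character leaves the
  # MP set unchanged and raises m and TL equally
  cm2 <- apply_edits(g$matrix, matrix_edit(
    "add-character", character = 16, ordered = TRUE,
    cells = setNames(c("1", rep("0", 6)), g$matrix$taxa),
    note = "autapomorphy"))
  r2 <- branch_and_bound(cm2)
  expect_identical(vapply(mp_trees(r), ape::write.tree, ""),
                   vapply(mp_trees(r2), ape::write.tree, ""))
  expect_identical(r2$TL, r$TL + 1L)
  expect_identical(sum(r2$m), sum(r$m) + 1L)
  expect_gte(tree_stats(r2)$CI, st$CI)
})

test_that("polymorphism-as-both costing adds the within-terminal span", {
  cells <- matrix(c("02", "0", "1", "2"), ncol = 1,
                  dimnames = list(paste0("t", 1:4), NULL))
  cm <- character_matrix(cells, ordered = TRUE)
  edges <- rbind(c(1L, 5L), c(2L, 5L), c(5L, 6L), c(3L, 6L), c(4L, 6L))
  lu <- tree_length(edges, cm, polymorphism = "uncertainty")
  lp <- tree_length(edges, cm, polymorphism = "polymorphism")
  expect_identical(lp, lu + 2L)  # span of {0,2}
})

test_that("consensus trees match brute-force clade counting", {
  one <- ape::read.tree(text = "(t1,(t2,(t3,(t4,t5))));")
  c1 <- consensus_trees(one, "strict")
  expect_identical(ape::write.tree(c1$tree), ape::write.tree(one))
  # two trees differing in one clade: strict collapses exactly it
  a <- ape::read.tree(text = "(t1,(t2,(t3,(t4,t5))));")
  b <- ape::read.tree(text = "(t1,(t2,(t4,(t3,t5))));")
  cs <- consensus_trees(c(a, b), "strict")
  expect_identical(cs$tree$Nnode, a$Nnode - 1L)
  # majority-rule frequencies equal direct bipartition counts
  set.seed(90)
  trees <- lapply(1:7, function(i) {
    e <- random_edges(6)
    ape::read.tree(text = unguis:::canonical_newick(e, paste0("t", 1:6),
                                                    "t1"))
  })
  class(trees) <- "multiPhylo"
  cm_ <- consensus_trees(trees, "majority", threshold = 0.5)
  freqs <- clade_frequencies(trees)
  for (k in seq_along(cm_$support)) {
    node <- length(cm_$tree$tip.label) + k
    tips <- cm_$tree$tip.label[unguis:::descendant_tips(cm_$tree, node)]
    key <- paste(sort(tips), collapse = "|")
    want <- if (key %in% names(freqs)) unname(freqs[[key]]) else 1
    expect_equal(cm_$support[k], want, tolerance = 1e-12,
                 label = paste("clade", key))
  }
  # mismatched taxon sets are refused
  odd <- ape::read.tree(text = "(x1,(t2,(t3,(t4,t5))));")
  expect_error(consensus_trees(c(a, odd)), "identical taxon set")
})

test_that("low-homoplasy simulations recover the generating tree", {
  hits <- 0
  for (rep in 1:25) {
    g <- gen_character_matrix(evol_spec(7, 25, nstates = 5,
                                        change_prob = 0.01),
                              seed = 9100 + rep)
    r <- branch_and_bound(g$matrix, collect_trees = FALSE)
    if (tree_length(g$tree, g$matrix) == r$TL) hits <- hits + 1
  }
  # smoke-scale check: at n = 25 replicates binomial noise around the
  # full-scale 95% recovery rate allows a few misses; the definitive
  # 100-replicate experiment runs with the acceptance checks
  expect_gte(hits, 21)
})
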