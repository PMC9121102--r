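# 21-sample block-structured expression fixture: three planted blocks of
# co-expressed genes plus independent noise genes.
block_fixture <- function(seed = 451, n_per_block = 8, n_noise = 8,
                          noise_sd = 0.15) {
  set.seed(seed)
  tissue_of <- rep(TISSUES, each = 3)
  profiles <- rbind(c(20, 20, 20, 20, 20, 20, 200),
                    c(180, 20, 20, 180, 20, 20, 20),
                    c(20, 20, 180, 20, 20, 180, 20))
  genes <- list()
  labels <- character(0)
  for (b in 1:3) {
    for (g in seq_len(n_per_block)) {
      mu <- profiles[b, ][match(tissue_of, TISSUES)]
      genes[[length(genes) + 1L]] <- mu * exp(rnorm(21, 0, noise_sd))
      labels <- c(labels, paste0("block", b))
    }
  }
  for (g in seq_len(n_noise)) {
    # flat expected profile: sample noise only, uncorrelated with blocks
    genes[[length(genes) + 1L]] <- 40 * exp(rnorm(21, 0, 4 * noise_sd))
    labels <- c(labels, "none")
  }
  mat <- do.call(rbind, genes)
  rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  colnames(mat) <- paste0(tissue_of, "_", rep(1:3, times = 7))
  list(mat = mat, labels = setNames(labels, rownames(mat)),
       tissue_of = tissue_of)
}

test_that("gene filtering removes zero variance and missing rows", {
  m <- matrix(rnorm(63), 3, 21,
              dimnames = list(c("ok", "const", "holey"), NULL))
  m["const", ] <- 5
  m["holey", 1:3] <- NA                    # 3/21 = 14.3% missing
  f <- filter_genes(m)
  expect_identical(rownames(f$mat), "ok")
  expect_setequal(f$removed$gene, c("const", "holey"))
  # 2/21 = 9.5% missing is kept
  m2 <- m[c("ok", "holey"), ]
  m2["holey", ] <- rnorm(21)
  m2["holey", 1:2] <- NA
  expect_identical(nrow(filter_genes(m2)$mat), 2L)
  expect_error(filter_genes(m["const", , drop = FALSE]), "all genes")
})

test_that("soft adjacency and TOM reproduce hand-computed values", {
  # |cor| = 0.5 at beta = 8
  expect_equal(abs(0.5)^8, 0.00390625)
  set.seed(452)
  x <- rnorm(10)
  m <- rbind(a = x, b = 2 * x + 1, c = rnorm(10))
  adj <- adjacency(m, beta = 8)
  expect_equal(adj["a", "b"], 1)
  expect_equal(adj["a", "c"], abs(cor(x, m["c", ]))^8)
  expect_lt(max(abs(adj - t(adj))), 1e-12)

  # 2-gene network, a_12 = 0.5: no shared neighbors, k_i = 0.5, so
  # TOM_12 = (0 + 0.5)/(0.5 + 1 - 0.5) = 0.5
  a2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(topological_overlap(a2)[1, 2], 0.5)
  # zero off-diagonal adjacency -> zero off-diagonal TOM
  a0 <- diag(2)
  expect_equal(topological_overlap(a0)[1, 2], 0)
  # 3-node case against the formula computed by hand
  a3 <- matrix(c(1, .5, .2, .5, 1, .4, .2, .4, 1), 3)
  t12 <- (.2 * .4 + .5) / (min(.5 + .2, .5 + .4) + 1 - .5)
  expect_equal(topological_overlap(a3)[1, 2], t12)
  # TOM stays in [0, 1] on random unsigned adjacencies
  set.seed(453)
  r <- abs(cor(matrix(rnorm(200), 20)))^8
  diag(r) <- 1
  tom <- topological_overlap(r)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
})

test_that("planted blocks are detected and noise genes stay grey", {
  fx <- block_fixture()
  adj <- adjacency(fx$mat, beta = 8)
  tom <- topological_overlap(adj)
  mods <- detect_modules(tom)
  # three modules, labels ordered by size; noise genes unassigned
  expect_setequal(setdiff(unique(mods), "grey"), c("M1", "M2", "M3"))
  expect_true(all(mods[fx$labels == "none"] == "grey"))
  # agreement with the planted partition
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(mods[fx$labels != "none"],
                                   fx$labels[fx$labels != "none"])
  expect_gte(ari, 0.99)
  # degenerate cut height: everything unassigned
  cfg0 <- coexpress_config()
  cfg0$cut_height <- 1e-9
  expect_true(all(detect_modules(tom, cfg0) == "grey"))
  # label partition is invariant under row shuffles
  set.seed(454)
  perm <- sample(nrow(fx$mat))
  mods_p <- detect_modules(topological_overlap(
    adjacency(fx$mat[perm, ], beta = 8)))
  expect_gte(mclust::adjustedRandIndex(mods_p[names(mods)], mods), 0.999)
})

test_that("eigengenes behave like oriented first principal components", {
  fx <- block_fixture()
  mods <- setNames(fx$labels, names(fx$labels))
  mods[mods == "none"] <- "grey"
  eig <- module_eigengene(fx$mat, mods)
  # a module of near-identical profiles: eigengene tracks the profile
  e1 <- eig["block1", ]
  prof <- colMeans(t(scale(t(fx$mat[fx$labels == "block1", ]))))
  expect_gt(cor(e1, prof), 0.99)
  # sign orientation: flipping all genes flips the eigengene
  flip <- -fx$mat[fx$labels == "block1", , drop = FALSE] +
    max(fx$mat)                            # keep values positive
  eig_f <- module_eigengene(flip, mods[fx$labels == "block1"])
  expect_lt(cor(eig_f["block1", ], e1), -0.99)
  # PC1 explains at least as much variance as any other component
  z <- t(scale(t(fx$mat[fx$labels == "block1", ])))
  sv <- svd(z)
  expect_true(all(sv$d[1] >= sv$d[-1]))
  # single-gene module: standardized profile
  single <- mods
  single[1] <- "solo"
  eig_s <- module_eigengene(fx$mat, single)
  expect_equal(unname(eig_s["solo", ]),
               as.numeric(scale(fx$mat[1, ])), tolerance = 1e-12)
})

test_that("module-trait correlation flags the planted tissue module", {
  fx <- block_fixture()
  mods <- setNames(fx$labels, names(fx$labels))
  mods[mods == "none"] <- "grey"
  eig <- module_eigengene(fx$mat, mods)
  mt <- module_trait(eig, fx$tissue_of)
  row <- mt[mt$module == "block1" & mt$tissue == "P", ]
  expect_gte(abs(row$r), 0.75)
  expect_lt(row$p, 0.01)
  expect_true(row$retained)
  # an eigengene orthogonal to every indicator retains nothing
  eig0 <- matrix(rep(c(-1, 1), length.out = 21), 1,
                 dimnames = list("flat", NULL))
  mt0 <- module_trait(eig0, fx$tissue_of)
  expect_false(any(mt0$retained))
})

test_that("kME ranks hub genes like independently computed correlations", {
  fx <- block_fixture()
  mods <- setNames(fx$labels, names(fx$labels))
  mods[mods == "none"] <- "grey"
  eig <- module_eigengene(fx$mat, mods)
  hubs <- suppressWarnings(kme_hubs(fx$mat, eig, mods, n_hubs = 9))
  expect_warning(
    kme_hubs(fx$mat, eig["block1", , drop = FALSE],
             mods[mods == "block1"], n_hubs = 9),
    "returning all")
  b1 <- hubs[hubs$module == "block1", ]
  ref <- sort(vapply(names(mods)[mods == "block1"], function(g) {
    cor(fx$mat[g, ], eig["block1", ])
  }, numeric(1)), decreasing = TRUE)
  expect_equal(b1$kme, unname(ref[seq_len(nrow(b1))]), tolerance = 1e-12)
})

test_that("module miRNAs are traced with brute-force degrees", {
  inter <- data.frame(
    mirna_id = c("m1", "m1", "m2", "m3"),
    transcript_id = c("g1", "g2", "g9", "g1"), stringsAsFactors = FALSE)
  tr <- trace_module_mirnas(c("g1", "g2"), inter)
  expect_identical(nrow(tr$edges), 3L)
  expect_identical(tr$degree[["m1"]], 2L)
  expect_identical(tr$degree[["m3"]], 1L)
  expect_identical(nrow(trace_module_mirnas(character(0), inter)$edges), 0L)
})
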