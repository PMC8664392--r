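test_that("quantization bins uniformly and conserves valid cells", {
  m <- matrix(0:15, 4, 4)
  q <- quantize_map(m, 16L)
  expect_equal(sort(unique(as.vector(q$levels))), 1:16)
  expect_equal(as.vector(table(q$levels)), rep(1L, 16))

  const <- quantize_map(matrix(3, 3, 3), 16L)
  expect_true(all(const$levels == 1L))

  with_na <- matrix(stats::runif(30), 5, 6)
  with_na[c(2, 9, 17)] <- NA
  qn <- quantize_map(with_na, 8L)
  expect_equal(sum(!is.na(qn$levels)), 27)
  expect_equal(sum(table(qn$levels)), 27)
  expect_error(quantize_map(matrix(NA_real_, 2, 2)), "no valid cells")
})

test_that("co-occurrence counting matches hand-derived 2x2 cases", {
  q <- quantize_map(matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE), 2L)
  # rows (1,1) and (2,2): horizontal pairs are (1,1) and (2,2)
  g0 <- compute_glcm(q, 0)
  expect_equal(g0, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  # vertical pairs are (1,2) twice: symmetric off-diagonal mass 1
  g90 <- compute_glcm(q, 90)
  expect_equal(g90, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(sum(g0), 1)
})

test_that("GLCM is symmetric, normalized and skips invalid pairs", {
  set.seed(4)
  for (i in 1:20) {
    v <- matrix(stats::runif(64), 8, 8)
    v[sample(64, 10)] <- NA
    q <- quantize_map(v, 6L)
    for (ang in c(0, 45, 90, 135)) {
      g <- compute_glcm(q, ang)
      expect_equal(sum(g), 1)
      expect_equal(g, t(g))
      expect_equal(g, oracle_glcm(q$levels, 6L, ang))
    }
  }
  qa <- quantize_map(matrix(c(1, NA, NA, 2), 2, 2), 2L)
  expect_error(compute_glcm(qa, 45), "no valid pixel pairs")
})

test_that("texture features match hand-evaluated and brute-force values", {
  ident <- matrix(0, 4, 4); ident[2, 2] <- 1
  f <- glcm_features(ident)
  expect_equal(unname(f), c(0, 0, 1, 1))   # CON 0, COR 0 (sigma=0), ENE 1, HOM 1

  unif2 <- matrix(0.25, 2, 2)
  f2 <- glcm_features(unif2)
  expect_equal(f2[["con"]], 0.5)
  expect_equal(f2[["cor"]], 0)
  expect_equal(f2[["ene"]], 0.25)
  expect_equal(f2[["hom"]], 0.75)

  expect_error(glcm_features(matrix(0.3, 2, 2)), "normalized")

  set.seed(5)
  for (i in 1:100) {
    ng <- sample(2:8, 1)
    g <- matrix(stats::rexp(ng * ng), ng, ng)
    g <- (g + t(g)) / 2
    g <- g / sum(g)
    expect_equal(glcm_features(g), oracle_glcm_features(g), tolerance = 1e-12)
  }
})

test_that("feature ranges hold on random quantized maps", {
  set.seed(6)
  for (i in 1:50) {
    q <- quantize_map(matrix(stats::rnorm(100), 10, 10), 16L)
    tx <- texture_of_quantized(q)
    expect_gte(tx[["con"]], 0)
    expect_true(tx[["cor"]] >= -1 && tx[["cor"]] <= 1)
    expect_true(tx[["ene"]] > 0 && tx[["ene"]] <= 1)
    expect_true(tx[["hom"]] > 0 && tx[["hom"]] <= 1)
  }
})

test_that("angle-averaged features survive 90-degree rotation", {
  set.seed(7)
  m <- matrix(stats::rnorm(48), 6, 8)
  rot <- t(m[nrow(m):1, ])
  expect_equal(texture_of_map(m), texture_of_map(rot), tolerance = 1e-12)
})

test_that("checkerboard extremizes contrast and homogeneity", {
  # among all 4x4 two-level arrangements with 8 ones, the checkerboard has
  # maximal angle-0/90 contrast and minimal homogeneity
  board <- matrix(rep(c(1, 2), 8), 4, 4)
  board[, c(2, 4)] <- 3 - board[, c(2, 4)]
  tx_board <- texture_of_map(board, n_levels = 2L, angles = c(0, 90))
  combos <- utils::combn(16, 8)
  worst_con <- -Inf; best_hom <- Inf
  for (i in seq_len(ncol(combos))) {
    m <- matrix(1, 4, 4); m[combos[, i]] <- 2
    if (length(unique(as.vector(m))) < 2) next
    tx <- texture_of_map(m, n_levels = 2L, angles = c(0, 90))
    worst_con <- max(worst_con, tx[["con"]])
    best_hom <- min(best_hom, tx[["hom"]])
  }
  expect_equal(tx_board[["con"]], worst_con)
  expect_equal(tx_board[["hom"]], best_hom)
})

test_that("local texture maps localize a two-region boundary", {
  v <- matrix(0, 15, 15)
  v[8:15, ] <- 10
  v <- v + matrix(stats::rnorm(225, 0, 0.1), 15, 15)
  pm <- parametric_map("MBF", v, matrix(TRUE, 15, 15))
  tm <- texture_map_of(pm, n_levels = 8L, neighborhood = 5L)
  expect_equal(dim(tm$con$values), c(15L, 15L))
  row_con <- rowMeans(tm$con$values, na.rm = TRUE)
  expect_lte(abs(which.max(row_con) - 7.5), 1.5)

  flat <- parametric_map("MBF", matrix(5 + stats::rnorm(225, 0, 1e-3), 15, 15),
                         matrix(TRUE, 15, 15))
  tf <- texture_map_of(flat, n_levels = 8L, neighborhood = 5L)
  expect_lt(stats::sd(tf$ene$values, na.rm = TRUE), 0.2)
  expect_error(texture_map_of(pm, neighborhood = 4L), "odd")
  expect_error(texture_map_of(pm, neighborhood = 31L), "larger than the map")
})

test_that("texture derivatives produce the 64 named third-order features", {
  set.seed(8)
  tmaps <- list()
  for (p in c("MBF", "SI", "ASD", "AAC")) {
    pm <- parametric_map(p, matrix(stats::rnorm(144), 12, 12),
                         matrix(TRUE, 12, 12))
    tmaps[[p]] <- texture_map_of(pm, n_levels = 8L, neighborhood = 5L)
  }
  d <- texture_derivative(tmaps)
  expect_length(d, 64L)
  expect_true(all(c("SI-COR-CON", "SI-COR-HOM") %in% names(d)))
  expect_false(any(grepl("^SS-|^SAS-", names(d))))
  expect_error(texture_derivative(tmaps[c("MBF", "SI")]), "ASD")

  # constant texture maps: every derivative contrast is zero
  const <- lapply(stats::setNames(c("MBF", "SI", "ASD", "AAC"),
                                  c("MBF", "SI", "ASD", "AAC")), function(p) {
    lapply(stats::setNames(c("con", "cor", "ene", "hom"),
                           c("con", "cor", "ene", "hom")), function(f) {
      parametric_map(paste0(p, "-", toupper(f)), matrix(1, 8, 8),
                     matrix(TRUE, 8, 8))
    })
  })
  dc <- texture_derivative(const)
  expect_true(all(dc[grepl("-CON$", names(dc))] == 0))
})
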