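test_that("per-phase block carries exactly 43 features and 96 directional evaluations", {
  set.seed(71)
  st <- make_stack(c(10, 10, 5))
  blk <- phase_block(st, "arterial_mid", G = 16)
  expect_identical(setdiff(names(blk), "phase_id"), feature_registry("block"))
  expect_equal(ncol(blk) - 1L, 43L)
  dirs <- attr(blk, "directional")
  expect_equal(dim(dirs), c(24L, 4L))
  expect_equal(length(dirs), 96L)  # 24 texture features x 4 directions
})

test_that("constant VOI: direction-free families are constant across angles", {
  st <- make_stack(c(8, 8, 8), intensities = array(100, c(8, 8, 8)))
  blk <- phase_block(st, "arterial_early", G = 8)
  dirs <- attr(blk, "directional")
  # co-occurrence of a one-level VOI is the same single state at every
  # angle, and zone features are replicated by construction; run-length
  # features legitimately differ across angles because diagonal chords of
  # a cube are shorter than axis-aligned ones
  iso <- grep("^(glcm|glzsm)_", rownames(dirs))
  expect_true(all(apply(dirs[iso, ], 1, function(r) diff(range(r)) == 0)))
  rl <- dirs[grep("^glrlm_", rownames(dirs)), ]
  expect_equal(rl[, "deg0"], rl[, "deg90"], tolerance = 1e-12)
  expect_equal(rl[, "deg45"], rl[, "deg135"], tolerance = 1e-12)
})

test_that("change_rate implements the relative-change definition", {
  expect_equal(change_rate(2, 3), 0.5)
  expect_equal(change_rate(7, 7), 0)
  expect_warning(z <- change_rate(0, 1), "zero-reference")
  expect_equal(z, 0)
  expect_error(change_rate(NaN, 1), "non-finite")
  expect_error(change_rate(1, Inf), "non-finite")
})

test_that("change rates are antisymmetric under phase swap", {
  set.seed(72)
  xr <- rnorm(200, 5, 2); xl <- rnorm(200, 5, 2)
  fw <- change_rate(xr, xl)   # l relative to r
  bw <- change_rate(xl, xr)   # r relative to l
  expect_equal(fw, -bw / (1 + bw), tolerance = 1e-10)
})

test_that("multiphase assembly yields 115 static + 108 delta features", {
  set.seed(73)
  co <- generate_cohort(phantom_config(n_per_class = 2, grid = 20,
                                       radius_range = c(4, 6), seed = 73))
  per_phase <- extract_features(co, G = 16)
  expect_equal(nrow(per_phase), 4 * 4)  # 4 cases x 4 phases
  feats <- assemble_features(per_phase)
  sets <- feature_sets(feats)
  meta <- c("case_id", "recist", "group")
  expect_equal(ncol(feats) - length(meta), 223L)
  expect_length(sets$S1, 7L)
  expect_length(sets$S2, 108L)
  expect_length(sets$S3, 108L)
  expect_length(sets$S4, 115L)
  expect_length(sets$S5, 223L)
  # set algebra: S3 inside S5, disjoint from S1 and from the static part
  expect_true(all(sets$S3 %in% sets$S5))
  expect_length(intersect(sets$S1, sets$S3), 0L)
  expect_length(intersect(sets$S4, sets$S3), 0L)
  expect_identical(sets$S5, c(sets$S4, sets$S3))
})

test_that("identical phases produce exactly zero deltas; assembly is pure", {
  set.seed(74)
  vox <- array(rnorm(8 * 8 * 4, 100, 12), c(8, 8, 4))
  st <- make_stack(c(8, 8, 4), intensities = vox)  # same volume, all phases
  blocks <- extract_features(list(st), G = 8)
  case <- assemble_case(blocks)
  delta_cols <- grep("__delta_", names(case), value = TRUE)
  expect_length(delta_cols, 108L)
  expect_true(all(as.numeric(case[1, delta_cols]) == 0))
  # purity: identical inputs give bit-identical vectors
  expect_identical(assemble_case(blocks), case)
  # missing phase errors by name
  expect_error(assemble_case(blocks[blocks$phase_id != "hepatobiliary", ]),
               "hepatobiliary")
})

test_that("per-phase intensity scaling leaves texture deltas unchanged", {
  set.seed(75)
  vox <- array(rnorm(10 * 10 * 4, 100, 15), c(10, 10, 4))
  st1 <- make_stack(c(10, 10, 4), intensities = vox)
  scaled <- lapply(tace_phases, function(p) vox * 3.7)
  names(scaled) <- tace_phases
  scaled$arterial_early <- vox  # scale one phase trio only
  st2 <- make_stack(c(10, 10, 4), intensities = scaled)
  b1 <- extract_features(list(st1), G = 8)
  b2 <- extract_features(list(st2), G = 8)
  tex <- feature_registry("texture")
  # range-relative quantization: per-phase texture identical despite scaling
  expect_equal(as.data.frame(b1[, tex]), as.data.frame(b2[, tex]),
               tolerance = 1e-10)
  d1 <- assemble_case(b1)
  d2 <- assemble_case(b2)
  tex_delta <- grep("^(glcm|glrlm|glzsm)_.*__delta_", names(d1), value = TRUE)
  expect_equal(as.data.frame(d1[, tex_delta]), as.data.frame(d2[, tex_delta]),
               tolerance = 1e-10)
})
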