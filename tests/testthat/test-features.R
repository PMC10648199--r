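test_that("periodicity feature obeys its closed form on simple inputs", {
  expect_equal(periodicity_feature(rep(0, 5), 3.6), 0)
  # a single non-zero term contributes its magnitude
  expect_equal(periodicity_feature(c(2.5, 0, 0, 0, 0), 3.6), 2.5)
  expect_equal(periodicity_feature(c(-2.5, 0, 0, 0, 0), 3.6), 2.5)
  expect_error(periodicity_feature(1:5, 0), "positive")
  # value frozen from an independent direct evaluation of the sum formula
  # for the hydropathy profile of "AILAV" at the helix period
  expect_equal(periodicity_feature(c(1.8, 4.5, 3.8, 1.8, 4.2), 3.6),
               4.55045627867897, tolerance = 1e-9)
})

test_that("periodicity of a harmonic input is phase-invariant over whole cycles", {
  # exact phase invariance holds when the analysis period completes an
  # integer number of cycles over the window (the conjugate-frequency sum
  # vanishes); 2.5 and 5/3 do so over five residues
  k <- 1:5
  for (T in c(2.5, 5 / 3, 1.25)) {
    vals <- vapply(seq(0, 2 * pi, length.out = 17), function(delta) {
      periodicity_feature(cos(2 * pi * k / T + delta), T)
    }, numeric(1))
    expect_lt(max(vals) - min(vals), 1e-9)
  }
})

test_that("the matched input period maximizes the phase-averaged response", {
  # analysed at the helix period, harmonic inputs of matching period give
  # the largest mean-square response (individual phases can be distorted
  # by the short five-residue window, hence the phase average)
  k <- 1:5
  deltas <- seq(0, 2 * pi, length.out = 9)[-9]
  input_periods <- c(2, 2.5, 3, 3.6, 4.5, 5)
  resp <- vapply(input_periods, function(Tin) {
    mean(vapply(deltas, function(d) {
      periodicity_feature(cos(2 * pi * k / Tin + d), 3.6)^2
    }, numeric(1)))
  }, numeric(1))
  expect_equal(input_periods[which.max(resp)], 3.6)
})

test_that("the default registry yields 76 network inputs per window after selection-scale pruning is disabled", {
  # compact registry: one scale family restricted to a 76-feature layout
  reg76 <- feature_registry(
    periodicity = tibble::tibble(scale_id = "KYTJ820101", period = 3.6),
    products = FALSE,
    occ_windows = "1-5"
  )
  # 35 positional + 7 means + 1 periodicity + 16 + 16 occurrence + 1 unseen
  expect_equal(nrow(reg76), 76)
  expect_equal(sum(reg76$provenance == "occurrence"), 33)
})

test_that("registry feature ids are unique and parameter-complete", {
  reg <- feature_registry()
  expect_equal(anyDuplicated(reg$feature_id), 0L)
  occ <- reg[reg$provenance == "occurrence", ]
  expect_true(all(!is.na(occ$window)))
  pos <- reg[reg$transform == "positional", ]
  expect_true(all(!is.na(pos$position) & !is.na(pos$scale_id)))
})

test_that("occurrence tables compute population statistics per class", {
  frag <- tibble::tibble(seq5 = c("AAAAA", "AAAAA", "CCCCC"))
  rm <- matrix(0, 3, 16, dimnames = list(NULL, paste0("rmsd_", pb_letters)))
  rm[, "rmsd_a"] <- c(1, 2, 5)
  frag <- dplyr::bind_cols(frag, tibble::as_tibble(rm))
  occ <- build_occurrence_table(frag)
  expect_equal(sort(occ$seq5), c("AAAAA", "CCCCC"))
  expect_equal(occ$mean_a[occ$seq5 == "AAAAA"], 1.5)
  expect_equal(occ$sd_a[occ$seq5 == "AAAAA"], 0.5)   # population convention
  expect_equal(occ$sd_a[occ$seq5 == "CCCCC"], 0)
  expect_true(occ$singleton[occ$seq5 == "CCCCC"])
  expect_equal(sum(occ$n), nrow(frag))               # counts conserved
  # empty input gives an empty table, not an error
  expect_equal(nrow(build_occurrence_table(frag[0, ])), 0)
})

test_that("subsequence windows pool fragments sharing the window", {
  frag <- tibble::tibble(seq5 = c("AADAA", "CCDCC"))
  rm <- matrix(1, 2, 16, dimnames = list(NULL, paste0("rmsd_", pb_letters)))
  frag <- dplyr::bind_cols(frag, tibble::as_tibble(rm))
  occ3 <- build_occurrence_table(frag, window = "3-3")
  expect_equal(occ3$seq5, "D")
  expect_equal(occ3$n, 2L)
  expect_error(build_occurrence_table(frag, window = "0-9"), "within 1-5")
})

test_that("feature computation is deterministic and traceable", {
  reg <- feature_registry(products = FALSE, occ_windows = NULL,
                          periodicity = tibble::tibble(scale_id = "KYTJ820101",
                                                       period = 3.6))
  frag <- tibble::tibble(seq5 = c("AILAV", "AILAV", "WWWWW"))
  f1 <- fragment_features(frag, reg)
  f2 <- fragment_features(frag, reg)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  expect_equal(unname(unlist(f1[1, -1])), unname(unlist(f1[2, -1])))
  expect_equal(f1$per3.6_KYTJ820101[1], 4.55045627867897, tolerance = 1e-9)
  kd <- c(A = 1.8, I = 4.5, L = 3.8, V = 4.2)
  expect_equal(f1$pos2_KYTJ820101[1], unname(kd["I"]))
  expect_equal(f1$mean_KYTJ820101[1], mean(kd[c("A", "I", "L", "A", "V")]))
})

test_that("unknown residues impute physchem values and mask occurrence", {
  reg <- feature_registry(products = FALSE, occ_windows = "1-5",
                          periodicity = tibble::tibble(scale_id = character(),
                                                       period = numeric()))
  occ <- build_occurrence_table(dplyr::bind_cols(
    tibble::tibble(seq5 = "AAAAA"),
    tibble::as_tibble(matrix(1, 1, 16, dimnames = list(NULL, paste0("rmsd_", pb_letters))))
  ))
  f <- fragment_features(tibble::tibble(seq5 = c("AAXAA", "AAAAA")), reg,
                         occurrence = occ)
  scales <- aa_scales()
  kd_mean <- mean(scales$value[scales$scale_id == "KYTJ820101"])
  expect_equal(f$pos3_KYTJ820101[1], kd_mean)
  expect_equal(f$occ_unseen_15, c(1, 0))
  mask <- attr(f, "mask")
  expect_true(mask[1, "occmean_a"])
  expect_false(mask[2, "occmean_a"])
  # unseen 5-mers back off to the table-wide mean
  f2 <- fragment_features(tibble::tibble(seq5 = "CCCCC"), reg, occurrence = occ)
  expect_equal(f2$occmean_a, 1)
  expect_equal(f2$occ_unseen_15, 1)
  expect_error(fragment_features(tibble::tibble(seq5 = "AAAAA"), reg),
               "occurrence")
})

test_that("unknown scales are rejected", {
  reg <- feature_registry(scales = aa_scales(), products = FALSE,
                          occ_windows = NULL)
  reg$scale_id[1] <- "NOPE"
  expect_error(fragment_features(tibble::tibble(seq5 = "AAAAA"), reg),
               "unknown or incomplete scale")
})

test_that("window expansion multiplies the base width by the number of offsets", {
  # test registry of 10 base features
  reg <- feature_registry(scales = aa_scales()[aa_scales()$scale_id %in%
                                                 c("KYTJ820101", "GRAR740102"), ],
                          mean_scales = character(0),
                          periodicity = tibble::tibble(scale_id = character(),
                                                       period = numeric()),
                          products = FALSE, occ_windows = NULL)
  expect_equal(nrow(reg), 10)
  cfg <- fixture_config(n_chains = 1, length_range = c(20, 20), seed = 2)
  fr <- extract_fragments(generate_chain(cfg, length = 20))
  base <- fragment_features(fr, reg)
  wide <- window_expand(base)
  keys <- c("chain_id", "start", "center", "seq5")
  expect_equal(ncol(wide) - length(keys), 10 * 5)
  # interior rows need no padding; border rows repeat the nearest window
  pad <- attr(wide, "pad")
  expect_false(any(pad[3:(nrow(wide) - 2), ]))
  expect_true(pad[1, "offset-2"] && pad[1, "offset-1"])
  expect_true(pad[nrow(wide), "offset2"])
  first_block <- unlist(wide[1, paste0(reg$feature_id, "@-1")], use.names = FALSE)
  self_block <- unlist(wide[1, paste0(reg$feature_id, "@0")], use.names = FALSE)
  expect_equal(first_block, self_block)  # clamped to nearest valid window
  # interior offsets line up with the shifted rows
  expect_equal(unlist(wide[3, paste0(reg$feature_id, "@-2")], use.names = FALSE),
               unname(unlist(base[1, reg$feature_id])))
})

test_that("the 76-feature base layout expands to 380 columns", {
  reg76 <- feature_registry(
    periodicity = tibble::tibble(scale_id = "KYTJ820101", period = 3.6),
    products = FALSE, occ_windows = "1-5"
  )
  cfg <- fixture_config(n_chains = 1, length_range = c(15, 15), seed = 4)
  fr <- extract_fragments(generate_chain(cfg, length = 15))
  asg <- assign_pb(fr)
  occ <- occurrence_tables(asg, reg76)
  wide <- window_expand(fragment_features(asg, reg76, occurrence = occ))
  expect_equal(ncol(wide) - 4, 380)
})

test_that("AAindex flat files parse into long scale tables", {
  path <- system.file("extdata", "example_aaindex1.txt", package = "pblocks")
  sc <- read_aaindex(path)
  expect_equal(unique(sc$scale_id), c("KYTJ820101", "GRAR740102"))
  expect_equal(nrow(sc), 40)
  expect_equal(sc$value[sc$scale_id == "KYTJ820101" & sc$aa == "I"], 4.5)
  expect_equal(sc$value[sc$scale_id == "GRAR740102" & sc$aa == "V"], 5.9)
  # parsed values agree with the packaged table
  packaged <- aa_scales()
  merged <- merge(sc, packaged, by = c("scale_id", "aa"))
  expect_equal(merged$value.x, merged$value.y)
})
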