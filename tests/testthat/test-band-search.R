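test_that("index formulas evaluate correctly and flag degenerate samples", {
  sp <- spectra_set(c(500, 600, 700),
                    matrix(c(0.2, 0.3, 0.25), 1))
  expect_equal(index_values("SI", sp, c(500, 600)), 0.5)
  expect_equal(index_values("DI", sp, c(500, 600)), -0.1)
  expect_equal(index_values("PI", sp, c(500, 600)), 0.06)
  expect_equal(index_values("RI", sp, c(500, 600)), 2 / 3)
  expect_equal(index_values("NDI", sp, c(500, 600)), -0.2)
  expect_equal(index_values("TBI5", sp, c(500, 600, 700)), 0)  # Rk = (Ri+Rj)/2
  # TBI3 with Rj == Rk is flagged, not propagated
  sp2 <- spectra_set(c(500, 600, 700), matrix(c(0.2, 0.3, 0.3), 1))
  expect_true(is.nan(index_values("TBI3", sp2, c(500, 600, 700))))
  expect_error(index_values("DI", sp, c(500, 500)), "distinct")
  expect_error(index_values("DI", sp, c(500, 601)), "grid")
  expect_error(index_values("DI", sp, c(500, 600, 700)), "2 wavelengths")
})

test_that("scan matches the naive per-cell Pearson oracle for all ten forms", {
  td <- toy_scan_data(n = 30, B = 10)
  for (fm in c(TWO_BAND_FORMS, THREE_BAND_FORMS)) {
    m <- scan_index(fm, td$spectra, td$som)
    oracle <- naive_scan(fm, td$refl, td$som)
    expect_equal(is.na(m$r), is.na(oracle), info = fm)
    expect_lt(max(abs(m$r - oracle), na.rm = TRUE), 1e-12, label = fm)
    expect_identical(unname(which(m$valid)), which(!is.na(oracle)))
  }
})

test_that("maps satisfy the symmetry structure of their formulas", {
  td <- toy_scan_data(n = 25, B = 12, seed = 13)
  for (fm in c("DI", "NDI")) {
    m <- scan_index(fm, td$spectra, td$som)$r
    both <- !is.na(m) & !is.na(t(m))
    expect_equal(m[both], -t(m)[both], tolerance = 1e-15, info = fm)
  }
  for (fm in c("SI", "PI")) {
    m <- scan_index(fm, td$spectra, td$som)$r
    both <- !is.na(m) & !is.na(t(m))
    expect_equal(m[both], t(m)[both], tolerance = 1e-15, info = fm)
  }
})

test_that("chunked and unchunked triple scans are bit-identical", {
  td <- toy_scan_data(n = 20, B = 9, seed = 21)
  for (fm in c("TBI2", "TBI4")) {
    full <- scan_index(fm, td$spectra, td$som)
    chunked <- scan_index(fm, td$spectra, td$som, chunk_size = 2L)
    expect_identical(full$r, chunked$r, info = fm)
    expect_identical(full$valid, chunked$valid, info = fm)
  }
})

test_that("maps are invariant to positive rescaling of SOM", {
  td <- toy_scan_data(n = 20, B = 8, seed = 31)
  m1 <- scan_index("NDI", td$spectra, td$som)$r
  m2 <- scan_index("NDI", td$spectra, 3.7 * td$som)$r
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("top_candidates keeps the ceiling of the retained fraction by |r|", {
  td <- toy_scan_data(n = 30, B = 11, seed = 3)
  m <- scan_index("DI", td$spectra, td$som)
  n_valid <- sum(m$valid)
  cand <- top_candidates(m, fraction = 0.01)
  expect_equal(nrow(cand), ceiling(0.01 * n_valid))
  expect_equal(abs(cand$r_cal[1]), max(abs(m$r), na.rm = TRUE))
  # fraction 1 keeps everything; the kept set equals the oracle's sorted top
  all_cand <- top_candidates(m, fraction = 1)
  expect_equal(nrow(all_cand), n_valid)
  k <- 25
  topk <- top_candidates(m, fraction = k / n_valid)
  oracle_thresh <- sort(abs(m$r[m$valid]), decreasing = TRUE)[k]
  expect_true(all(abs(topk$r_cal) >= oracle_thresh))
  expect_error(top_candidates(m, fraction = 0), "fraction")
  expect_error(top_candidates(m, fraction = 1.2), "fraction")
})

test_that("select_optimal minimizes the cal/val correlation error", {
  td <- toy_scan_data(n = 40, B = 8, seed = 17)
  cal_idx <- 1:28; val_idx <- 29:40
  cal_sp <- spectra_set(td$spectra$wavelengths, td$refl[cal_idx, ])
  val_sp <- spectra_set(td$spectra$wavelengths, td$refl[val_idx, ])
  m <- scan_index("NDI", cal_sp, td$som[cal_idx])
  cand <- top_candidates(m, fraction = 0.2)
  sel <- select_optimal(cand, val_sp, td$som[val_idx])
  # minimality: recompute every candidate's err independently
  errs <- vapply(seq_len(nrow(cand)), function(i) {
    v <- index_values("NDI", val_sp, c(cand$wl_i[i], cand$wl_j[i]))
    abs(cand$r_cal[i] - cor(v, td$som[val_idx]))
  }, numeric(1))
  expect_equal(sel$err, min(errs), tolerance = 1e-12)
  # singleton pool returns itself
  one <- cand[1, , drop = FALSE]
  sel1 <- select_optimal(one, val_sp, td$som[val_idx])
  expect_equal(sel1$wl_i, one$wl_i)
  expect_equal(sel1$wl_j, one$wl_j)
  # direct comparison of two known errs
  two <- cand[order(errs)[c(3, 1)], , drop = FALSE]
  sel2 <- select_optimal(two, val_sp, td$som[val_idx])
  expect_equal(sel2$err, sort(errs)[1], tolerance = 1e-12)
})

test_that("slice views index the cube at the optimal combination", {
  td <- toy_scan_data(n = 20, B = 6, seed = 9)
  m <- scan_index("TBI1", td$spectra, td$som)
  cand <- top_candidates(m, fraction = 0.05)
  sel <- select_optimal(cand, td$spectra, td$som)
  sv <- slice_views(m, sel)
  pi_ <- match(sel$wl_i, m$wavelengths)
  pj <- match(sel$wl_j, m$wavelengths)
  pk <- match(sel$wl_k, m$wavelengths)
  expect_identical(sv$slice_k, m$r[, , pk])
  expect_identical(sv$slice_i, m$r[pi_, , ])
  expect_identical(sv$slice_j, m$r[, pj, ])
  # each optimal slice contains the optimal cell
  expect_equal(sv$slice_k[pi_, pj], m$r[pi_, pj, pk])
  # two-band export is the map itself
  m2 <- scan_index("DI", td$spectra, td$som)
  sel2 <- select_optimal(top_candidates(m2, 0.05), td$spectra, td$som)
  expect_identical(slice_views(m2, sel2)$map_r, m2$r)
})

test_that("scan input validation", {
  td <- toy_scan_data(n = 10, B = 5)
  expect_error(scan_index("DI", td$spectra, rep(1, 10)), "variance")
  expect_error(scan_index("XX", td$spectra, td$som), "unknown")
  expect_error(scan_index("DI", td$spectra, td$som[1:3]), "mismatch")
})
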