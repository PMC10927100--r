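test_that("a fixed seed reproduces the dataset bit for bit", {
  ds1 <- simulate_dataset(small_generator(seed = 3))
  ds2 <- simulate_dataset(small_generator(seed = 3))
  expect_identical(serialize(ds1, NULL, version = 3),
                   serialize(ds2, NULL, version = 3))
  ds3 <- simulate_dataset(small_generator(seed = 4))
  expect_false(identical(ds1$tools$values, ds3$tools$values))
})

test_that("the noise-free limit gives identical trait rows within a unit", {
  ds <- simulate_dataset(small_generator(seed = 5, noise_flip_rate = 0,
                                         missing_rate = 0))
  for (u in setdiff(unique(ds$nacs$macro_unit), "unassigned")) {
    rows <- ds$tools$values[ds$nacs$macro_unit == u, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(col) length(unique(col)) == 1L)))
  }
})

test_that("trait mismatch rates match the flip model", {
  eps <- 0.08
  ds <- simulate_dataset(generator_config(seed = 6, noise_flip_rate = eps,
                                          missing_rate = 0))
  vals <- ds$technology$values
  unit <- ds$nacs$macro_unit
  within <- c(); between <- c()
  for (u in setdiff(unique(unit), "unassigned")) {
    idx <- which(unit == u)
    oth <- which(unit != u & unit != "unassigned")
    for (i in idx[1:2]) {
      within <- c(within, mean(vals[i, ] != vals[idx[length(idx)], ]))
      between <- c(between, mean(vals[i, ] != vals[oth[1], ]))
    }
  }
  # expected within-unit mismatch 2e(1-e); between-unit strictly larger
  expect_equal(mean(within), 2 * eps * (1 - eps), tolerance = 0.25)
  expect_gt(mean(between), mean(within) * 2)
})

test_that("generator rejects invalid configurations", {
  expect_error(generator_config(p_in = 0.4), "p_in")
  expect_error(generator_config(noise_flip_rate = 0.6), "noise_flip_rate")
  expect_error(generator_config(missing_rate = 1), "missing_rate")
  expect_error(generator_config(n_nacs = 5, n_macro_units = 7), "n_nacs")
  expect_error(generator_config(shape_dispersion_by_slice =
                                  c(I = 1, II = 1, III = 1, IV = -1)),
               "positive")
  expect_error(generator_config(time_slice_weights = c(0, 0, 0, 0)),
               "weights")
})

test_that("generated registries have the promised shape", {
  ds <- simulate_dataset(generator_config(seed = 7))
  expect_identical(dim(ds$tools$values), c(86L, 24L))
  expect_identical(dim(ds$technology$values), c(86L, 52L))
  expect_identical(nrow(ds$regions), 16L)
  expect_true(all(ds$nacs$region %in% ds$regions$region))
  m <- outline_meta(ds$outlines)
  expect_true(all(m$time_slice %in% time_slice_levels()))
  # unassigned NACs carry no outlines; every planted unit does
  un <- ds$nacs$nac_id[ds$nacs$macro_unit == "unassigned"]
  expect_length(intersect(m$nac_id, un), 0L)
  counts <- table(unclass(ds$map)[m$nac_id])
  expect_setequal(names(counts), setdiff(macro_unit_levels(), "unassigned"))
  # expansion bookkeeping: 86 NACs, 2 spanning two slices -> 88 rows
  expect_equal(nrow(expand_timeslices(ds$tools)$values), 88L)
  # per-slice outline counts are balanced by construction
  expect_true(all(table(m$time_slice) == length(ds$outlines) / 4))
  expect_identical(site_quality_score(
    unlist(ds$sites[1, names(default_quality_rubric())])),
    ds$sites$quality_total[1])
})

test_that("simulated outlines shrink to their template as sigma -> 0", {
  fam <- shape_families()[["tanged_point"]]
  ref <- efa_inverse(fam$template, 128L)
  dev <- vapply(c(0.1, 1e-3, 1e-6), function(sg) {
    o <- simulate_outline(fam, sg, seed = 9)
    mean(sqrt(rowSums((o$coords - ref$coords)^2)))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 1e-5)
})

test_that("noisy outlines stay assignable to their family by nearest template", {
  fams <- shape_families()
  templ <- t(vapply(fams, function(f) as.numeric(t(f$template$coef)),
                    numeric(40)))
  hits <- 0L; total <- 0L
  for (nm in names(fams)) {
    for (s in 1:8) {
      o <- simulate_outline(fams[[nm]], 0.03, seed = 100 + s)
      co <- as.numeric(t(efa_forward(
        preprocess_outline(o, smooth_iterations = 0, k = 200), 10)$coef))
      total <- total + 1L
      hits <- hits + (names(fams)[which.min(
        sqrt(rowSums(sweep(templ, 2, co)^2)))] == nm)
    }
  }
  expect_gte(hits / total, 0.85)
})

test_that("each family template reconstructs to a simple closed curve", {
  for (f in shape_families()) {
    o <- efa_inverse(f$template, 128L)
    expect_gt(palaeotax:::.polygon_area(o$coords), 0.01)
  }
})

test_that("degenerate outline draws hit the retry cap with an error", {
  fam <- shape_families()[["simple_point"]]
  # collapse the template to a point: every draw has ~zero enclosed area
  fam$template$coef <- fam$template$coef * 1e-8
  fam$dispersion <- fam$dispersion * 1e-8
  expect_error(simulate_outline(fam, 1e-6, seed = 1, max_retry = 3L),
               "degenerate")
  expect_error(simulate_outline(shape_families()[[1]], -1), "sigma")
})
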