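test_that("trait matrices round-trip through CSV, byte-identically on rewrite", {
  vals <- rbind(c(1L, 0L, NA, 1L), c(0L, NA, 1L, 0L), c(1L, 1L, 0L, NA))
  colnames(vals) <- paste0("trait_", 1:4)
  tm <- tiny_traits(vals)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trait_matrix(tm, f1)
  rt <- read_trait_matrix(f1, "tools")
  expect_identical(rt$values, tm$values)
  expect_identical(rt$meta$time_slices, tm$meta$time_slices)
  write_trait_matrix(rt, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("trait reader rejects bad tokens, duplicates and empty files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("nac_id,region,time_slices,macro_unit,t1",
               "A,R01,I,unassigned,2"), f)
  expect_error(read_trait_matrix(f, "tools"), "non-tri-state.*'2'.*'A'")
  writeLines(c("nac_id,region,time_slices,macro_unit,t1",
               "A,R01,I,unassigned,1", "A,R01,II,unassigned,0"), f)
  expect_error(read_trait_matrix(f, "tools"), "duplicate nac_id")
  writeLines("nac_id,region,time_slices,macro_unit,t1", f)
  expect_error(read_trait_matrix(f, "tools"), "no data rows")
})

test_that("unknown tokens map to the explicit unknown state, never a number", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("nac_id,region,time_slices,macro_unit,t1,t2,t3",
               "A,R01,I,unassigned,n/a,NA,",
               "B,R01,I,unassigned,0,1,1"), f)
  tm <- read_trait_matrix(f, "tools")
  expect_identical(unname(tm$values["A", ]), rep(NA_integer_, 3))
  expect_identical(unname(tm$values["B", ]), c(0L, 1L, 1L))
})

test_that("time-slice expansion duplicates rows and preserves trait values", {
  vals <- rbind(c(1L, 0L), c(0L, 1L), c(1L, NA))
  colnames(vals) <- c("t1", "t2")
  tm <- tiny_traits(vals)
  tm$meta$time_slices <- c("II|III", "I", "III|IV")
  tm2 <- trait_matrix(tm$values, tm$meta, tm$domain)
  ex <- expand_timeslices(tm2)
  expect_equal(nrow(ex$values), 5L)   # 3 rows + 2 extra slices
  expect_identical(ex$meta$time_slices,
                   c("II", "III", "I", "III", "IV"))
  dup <- ex$values[startsWith(rownames(ex$values), "N01"), ]
  expect_identical(unname(dup[1, ]), unname(dup[2, ]))
  one <- expand_timeslices(tiny_traits(vals))
  expect_identical(one$values, tiny_traits(vals)$values)
})

test_that("macro-unit assignment validates coverage and labels", {
  vals <- matrix(c(1L, 0L, 0L, 1L), 2, dimnames = list(c("Hamb", "Ahr"),
                                                       c("t1", "t2")))
  tm <- tiny_traits(vals)
  map <- macrounit_map(c(Hamb = "Magdalenian s.l.", Ahr = "TPC"))
  tm <- assign_macrounits(tm, map)
  expect_identical(tm$meta$macro_unit, c("Magdalenian s.l.", "TPC"))
  expect_error(assign_macrounits(tm, macrounit_map(c(Hamb = "TPC"))),
               "not in macro-unit map.*Ahr")
  expect_error(macrounit_map(c(A = "NotAUnit")), "unknown macro-unit")
})

test_that("site quality scores respect the rubric and the 0-6 bound", {
  rub <- default_quality_rubric()
  expect_identical(site_quality_score(rub, rub), 6L)
  expect_identical(site_quality_score(rub * 0L, rub), 0L)
  expect_identical(
    site_quality_score(c(chronology = 1L, stratigraphy = 1L,
                         integrity = 0L, recency = 1L), rub), 3L)
  expect_error(site_quality_score(c(chronology = 3L, stratigraphy = 0L,
                                    integrity = 0L, recency = 0L), rub),
               "exceeds rubric")
  expect_error(site_quality_score(c(chronology = 1L), rub), "missing")
})

test_that("TPS and CSV outline encodings agree and survive round trips", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=4", "0 0", "1 0", "1 1", "0 1", "ID=sq1"), f)
  tps <- read_outlines(f, "tps")
  expect_length(tps, 1L)
  expect_equal(unname(tps[["sq1"]]$coords),
               cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  fc <- withr::local_tempfile(fileext = ".csv")
  write_outlines(tps, fc, "csv")
  csv <- read_outlines(fc, "csv")
  expect_equal(csv[["sq1"]]$coords, tps[["sq1"]]$coords)
  f2 <- withr::local_tempfile(fileext = ".tps")
  write_outlines(csv, f2, "tps")
  expect_equal(read_outlines(f2, "tps")[["sq1"]]$coords,
               tps[["sq1"]]$coords)
})

test_that("degenerate TPS blocks error and unmatched metadata warns", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=2", "0 0", "1 0", "ID=bad"), f)
  expect_error(read_outlines(f, "tps"), "fewer than 3")
  writeLines(c("LM=3", "0 0", "1 0", "1 1", "ID=tri"), f)
  meta <- data.frame(artefact_id = "other", nac_id = "X")
  expect_warning(read_outlines(f, "tps", metadata = meta),
                 "no metadata.*tri")
  got <- suppressWarnings(read_outlines(f, "tps", metadata = meta))
  expect_true(is.na(got[["tri"]]$nac_id))
})

test_that("outline metadata joins by artefact id", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 0", "1 1", "ID=tri"), f)
  meta <- data.frame(artefact_id = "tri", nac_id = "NAC001",
                     time_slice = "II", lat = 50.1, lon = 8.2)
  got <- read_outlines(f, "tps", metadata = meta)
  m <- outline_meta(got)
  expect_identical(m$nac_id, "NAC001")
  expect_identical(m$time_slice, "II")
  expect_equal(m$lat, 50.1)
})

test_that("exports round-trip and reject unsupported pairings", {
  d <- random_dist_matrix(5)
  f <- withr::local_tempfile(fileext = ".csv")
  export_results(d, f, "csv")
  back <- as.matrix(utils::read.csv(f, row.names = 1, check.names = FALSE))
  expect_equal(unclass(d), back, tolerance = 1e-12,
               ignore_attr = "metric")
  hc <- ward_tree(d)
  fn <- withr::local_tempfile(fileext = ".nwk")
  export_results(hc, fn, "newick")
  phy <- ape::read.tree(fn)
  expect_setequal(phy$tip.label, rownames(d))
  expect_error(export_results(hc, f, "csv"), "unsupported")
})
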