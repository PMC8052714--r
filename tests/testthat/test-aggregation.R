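test_that("triplet summation reproduces the printed example tables", {
  cancer <- load_example_quads("cancer_12A")
  healthy <- load_example_quads("healthy_10")
  t_c <- sum_triplets(cancer)
  t_h <- sum_triplets(healthy)
  il8_c <- t_c[modulator == "IP-10" & source == "CD3+" & target == "IL-8"]$value
  il8_h <- t_h[modulator == "IP-10" & source == "CD3+" & target == "IL-8"]$value
  expect_equal(round(il8_c, 2), 502.08)
  expect_equal(round(il8_h, 2), 183.33)
  # the raw-count path is what makes the healthy sum land on 183.33: summing
  # the printed 2-decimal values gives 183.32
  expect_equal(round(sum(healthy[modulator == "IP-10" & target == "IL-8"]$normalized), 2),
               183.32)
  # single-quad triplets keep their value
  cd3 <- t_c[modulator == "IP-10" & target == "CD3+"]$value
  expect_equal(round(cd3, 2), 100.00)
})

test_that("doublet and singlet sums match hand arithmetic on a 3-quad table", {
  qt <- hand_quads()  # values 50, 25, 12.5 over 48
  ms <- sum_doublets(qt, "modulator_source")
  expect_equal(ms[modulator == "M1" & source == "S1"]$value, 75)
  expect_equal(ms[is.na(modulator)]$value, 12.5)
  st <- sum_doublets(qt, "source_target")
  expect_equal(st[source == "S1" & target == "T1"]$value, 50)
  expect_equal(st[source == "S1" & target == "T2"]$value, 25)
  tm <- sum_doublets(qt, "target_modulator")
  expect_equal(tm[target == "T1" & modulator == "M1"]$value, 50)
  # all quads sharing one pair collapse to the grand total
  one <- hand_quads()
  one$modulator <- "M"; one$source <- "S"
  expect_equal(sum_doublets(one, "modulator_source")$value, 87.5)
  # singlet conservation per role
  for (role in c("modulator", "source", "target", "lsv")) {
    expect_equal(sum(sum_singlets(qt, role)$value), 87.5)
  }
})

test_that("the summation hierarchy conserves the grand total", {
  # re-normalize from the raw counts so the quad values are exact, not the
  # 2-decimal presentation numbers
  qt <- load_example_quads("cancer_12A")
  qt$normalized <- 100 * qt$raw_count / 48
  total <- sum(qt$normalized)
  expect_equal(sum(sum_triplets(qt)$value), total, tolerance = 1e-9)
  for (v in c("modulator_source", "source_target", "target_modulator")) {
    expect_equal(sum(sum_doublets(qt, v)$value), total, tolerance = 1e-9)
  }
  for (r in c("modulator", "source", "target", "lsv")) {
    expect_equal(sum(sum_singlets(qt, r)$value), total, tolerance = 1e-9)
  }
  # quad -> triplet -> doublet composes
  via_triplet <- sum_doublets(sum_triplets(qt), "modulator_source")
  direct <- sum_doublets(qt, "modulator_source")
  m <- merge(via_triplet, direct, by = c("modulator", "source"))
  expect_equal(m$value.x, m$value.y, tolerance = 1e-9)
})

test_that("cohort averaging treats absent quads as zero", {
  a <- hand_quads()
  avg1 <- average_cohort(list(a, a))
  expect_equal(avg1$value, a$normalized[match(
    paste(avg1$modulator, avg1$source, avg1$target, avg1$lsv),
    paste(a$modulator, a$source, a$target, a$lsv))])
  b <- hand_quads()[1]
  b$normalized <- 10
  avg2 <- average_cohort(list(b, hand_quads()[2]))
  expect_equal(avg2[!is.na(modulator) & target == "T1"]$value, 5)
  # permuting participants changes nothing
  expect_identical(average_cohort(list(a, b)), average_cohort(list(b, a)))
  expect_error(average_cohort(list()), "empty")
  # active-only mean divides by the occurrence count instead
  expect_equal(average_cohort(list(b, hand_quads()[2]), active_only = TRUE)[
    !is.na(modulator) & target == "T1"]$value, 10)
})

test_that("cohort differencing is antisymmetric and partitions by sign", {
  a <- average_cohort(list(hand_quads()))
  b2 <- hand_quads()
  b2$normalized <- c(10, 40, 12.5)
  b <- average_cohort(list(b2))
  d1 <- diff_cohorts(a, b)
  d2 <- diff_cohorts(b, a)
  expect_equal(d1$diff$value, -d2$diff$value)
  expect_equal(d1$diff$value, c(12.5 - 12.5, 50 - 10, 25 - 40))
  got <- merge(d1$positive, d1$negative,
               by = c("modulator", "source", "target", "lsv"), all = TRUE)
  got[is.na(got)] <- 0
  expect_equal(got$value.x + got$value.y,
               d1$diff[value != 0]$value)
  # identical cohorts difference to zero
  d0 <- diff_cohorts(a, a)
  expect_true(all(d0$diff$value == 0))
  expect_equal(nrow(d0$positive), 0L)
})

test_that("top doublets ranks differences with deterministic ties", {
  set.seed(4)
  quads <- structure(data.table::data.table(
    modulator = rep(sprintf("M%02d", 1:12), each = 1),
    source = "S", target = "T", lsv = "L",
    raw_count = 1L, participant = "p", cohort = "c"),
    class = c("quad_table", "data.table", "data.frame"))
  quads <- normalize_counts(quads, 48)
  quads$normalized <- seq(12, 1)
  a <- average_cohort(list(quads))
  zero <- average_cohort(list(quads))
  zero$value <- 0
  cmp <- diff_cohorts(a, zero)
  top <- top_doublets(cmp, n = 10L)
  expect_equal(nrow(top), 10L)
  expect_equal(top$value, seq(12, 3))
  expect_equal(top$modulator[1:2], c("M01", "M02"))
})

test_that("flow export writes parseable DOT and JSON with correct sums", {
  qt <- hand_quads()
  out <- file.path(tempdir(), "flowtest")
  res <- export_flow(qt, out)
  dot <- readLines(res$dot)
  expect_equal(sum(grepl("shape=octagon", dot)), 2L)  # M1 and n.a.
  expect_equal(sum(grepl("shape=circle", dot)), 2L)   # S1, S2
  expect_equal(sum(grepl("->", dot, fixed = TRUE)), 2L)
  j <- jsonlite::read_json(res$json, simplifyVector = TRUE)
  expect_equal(sum(j$edges$value), 87.5)
  expect_setequal(j$nodes$sources$name, c("S1", "S2"))
  # empty table gives a valid empty graph
  empty <- hand_quads()[0]
  res0 <- export_flow(empty, file.path(tempdir(), "flowempty"))
  expect_true(file.exists(res0$dot))
  expect_equal(sum(grepl("->", readLines(res0$dot), fixed = TRUE)), 0L)
  # all-zero differences carry no colored edges
  a <- average_cohort(list(qt))
  dz <- diff_cohorts(a, a)
  resz <- export_flow(dz, file.path(tempdir(), "flowzero"))
  dotz <- readLines(resz$dot)
  expect_false(any(grepl("forestgreen|red3", dotz)))
})
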