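test_that("CNAB is the frequency-weighted non-stem copy deviation", {
  freqs <- tibble::tibble(clone = c("a", "b"), frequency = c(0.6, 0.4))
  evs <- tibble::tibble(
    clone = c("a", "b", "b"),
    event = c("g1", "g1", "l1"),
    copy_deviation = c(1, 1, -1)
  )
  expect_equal(cnab(freqs, evs), 0.6 * 1 + 0.4 * 2)
  # a stem-only tumor has zero burden
  stem_only <- tibble::tibble(clone = "a", frequency = 1)
  stem_evs <- tibble::tibble(clone = "a", event = c("s1", "s2"),
                             copy_deviation = c(1, -1))
  expect_equal(cnab(stem_only, stem_evs, stem_events = c("s1", "s2")), 0)
  # malformed frequencies are rejected
  expect_error(
    cnab(tibble::tibble(clone = "a", frequency = 0.7), evs),
    "sum to 1"
  )
  expect_error(
    cnab(tibble::tibble(clone = character(0), frequency = numeric(0)), evs),
    "non-empty"
  )
})

test_that("CNAB is linear in clone frequencies", {
  evs <- tibble::tibble(
    clone = c("a", "b", "b", "b"),
    event = c("e1", "e2", "e3", "e4"),
    copy_deviation = c(2, 1, -1, 1)
  )
  pure_a <- cnab(tibble::tibble(clone = "a", frequency = 1), evs)
  pure_b <- cnab(tibble::tibble(clone = "b", frequency = 1), evs)
  mixed <- cnab(tibble::tibble(clone = c("a", "b"),
                               frequency = c(0.5, 0.5)), evs)
  expect_equal(mixed, (pure_a + pure_b) / 2)
})

test_that("Simpson's diversity index matches its closed form", {
  expect_equal(simpson_diversity(1), 0)
  expect_equal(simpson_diversity(c(0.5, 0.5)), 0.5)
  expect_equal(simpson_diversity(rep(0.1, 10)), 0.9)
  expect_error(simpson_diversity(c(0.5, 0.4)), "sum to 1")
})

test_that("Simpson's index is bounded by and maximized at uniformity", {
  set.seed(9)
  for (k in 2:5) {
    uniform <- simpson_diversity(rep(1 / k, k))
    expect_equal(uniform, 1 - 1 / k)
    for (r in 1:50) {
      f <- rexp(k)
      f <- f / sum(f)
      expect_lte(simpson_diversity(f), uniform + 1e-12)
      expect_gte(simpson_diversity(f), 0)
    }
  }
})

test_that("private-aberration fraction counts units unique to one tumor", {
  # clone-level: tumor1 has X (private) and Y (shared with tumor2)
  tumors <- list(
    tumor1 = list(c("s", "x"), c("s", "y")),
    tumor2 = list(c("s", "y"), c("s", "z"))
  )
  pf <- private_aberration_fraction(tumors, stem_events = "s")
  expect_equal(pf$private_fraction[pf$tumor_id == "tumor1"], 0.5)
  expect_equal(pf$private_fraction[pf$tumor_id == "tumor2"], 0.5)
  # fully shared clones: zero everywhere
  shared <- list(t1 = list(c("a"), c("b")), t2 = list(c("a"), c("b")))
  expect_equal(private_aberration_fraction(shared)$private_fraction, c(0, 0))
  expect_error(private_aberration_fraction(tumors[1]), "At least two")
})

test_that("event-level private fractions use the overlap matching rule", {
  t1 <- tibble::tibble(
    chrom = c("chr1", "chr2"), start = c(0, 0), end = c(10e6, 10e6),
    direction = c("loss", "gain")
  )
  t2 <- tibble::tibble(
    chrom = "chr1", start = 1e6, end = 11e6, direction = "loss"
  )
  pf <- private_aberration_fraction(list(a = t1, b = t2), unit = "events")
  expect_equal(pf$private_fraction[pf$tumor_id == "a"], 0.5)
  expect_equal(pf$private_fraction[pf$tumor_id == "b"], 0)
})

test_that("planted private/shared clone design is recovered exactly", {
  tumors <- list(
    p1 = list(c("stem", "u1"), c("stem", "shared")),
    p2 = list(c("stem", "u2"), c("stem", "shared")),
    p3 = list(c("stem", "u3"), c("stem", "u4"))
  )
  pf <- private_aberration_fraction(tumors, stem_events = "stem")
  expect_equal(pf$private_fraction, c(0.5, 0.5, 1))
})

test_that("fish-plot data validates nesting and interpolates linearly", {
  parents <- c(root = NA, kid1 = "root", kid2 = "root")
  good <- tibble::tibble(
    time = c(0, 0, 0, 10, 10, 10),
    clone = rep(c("root", "kid1", "kid2"), 2),
    frequency = c(1, 0.3, 0.4, 1, 0.6, 0.2)
  )
  fp <- fishplot_data(good, parents, grid_points = 21)
  expect_s3_class(fp, "fishplot_data")
  k1 <- fp$trajectories |> dplyr::filter(clone == "kid1")
  expect_equal(k1$frequency[k1$time == 5], 0.45) # linear midpoint
  bad <- good
  bad$frequency[good$time == 0 & good$clone == "kid2"] <- 0.8 # 0.3+0.8 > 1
  expect_error(fishplot_data(bad, parents), "Nesting violation")
})

test_that("clones absent at a time point drop to zero with an emergence point", {
  parents <- c(root = NA, kid = "root")
  tb <- tibble::tibble(
    time = c(0, 10, 10, 20),
    clone = c("root", "root", "kid", "root"),
    frequency = c(1, 1, 0.6, 1)
  )
  fp <- fishplot_data(tb, parents, grid_points = 41)
  kid <- fp$trajectories |> dplyr::filter(clone == "kid")
  expect_equal(kid$frequency[kid$time == 0], 0)
  expect_equal(kid$frequency[kid$time == 5], 0) # before the emergence midpoint
  expect_equal(kid$frequency[kid$time == 10], 0.6)
  expect_equal(kid$frequency[kid$time == 20], 0) # absent later: back to zero
})

test_that("fish-plot JSON serialisation round-trips the trajectories", {
  parents <- c(root = NA, kid = "root")
  tb <- tibble::tibble(
    time = c(0, 10, 10), clone = c("root", "root", "kid"),
    frequency = c(1, 1, 0.5)
  )
  fp <- fishplot_data(tb, parents, grid_points = 11)
  path <- withr::local_tempfile(fileext = ".json")
  write_fishplot_json(fp, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(back$clones, c("root", "kid"))
  expect_equal(back$frequencies$root, rep(1, 11))
})
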