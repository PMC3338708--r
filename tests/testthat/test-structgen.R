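test_that("homopolymer collapse reaches the compact cuboid with adjacent termini", {
  p <- collapse_homopolymer(8, c(2, 2, 2), seed = 1)
  expect_s3_class(p, "parent_structure")
  expect_equal(nrow(compute_contacts(p)), 5L)
  expect_equal(sum((p$coords[1, ] - p$coords[8, ])^2), 1)

  p18 <- collapse_homopolymer(18, c(2, 3, 3), seed = 2)
  expect_equal(nrow(compute_contacts(p18)), 16L)

  expect_error(collapse_homopolymer(10, c(2, 2, 2), seed = 1), "volume")

  # deterministic given the seed
  q1 <- collapse_homopolymer(18, c(2, 3, 3), seed = 7)
  q2 <- collapse_homopolymer(18, c(2, 3, 3), seed = 7)
  expect_identical(q1$coords, q2$coords)
  expect_false(identical(q1$coords, p18$coords))
})

test_that("parent selection picks the contact-order extremes", {
  a <- compact_cuboid_path(c(2, 3, 3), label = "a")
  expect_identical(select_parents_by_co(list(a), "high")$label, "a")

  pool <- lapply(1:6, function(s) collapse_homopolymer(24, c(2, 3, 4),
                                                       seed = s))
  cos <- vapply(pool, function(p) contact_order(compute_contacts(p)),
                numeric(1))
  hi <- select_parents_by_co(pool, "high")
  lo <- select_parents_by_co(pool, "low")
  expect_equal(attr(hi, "co"), max(cos))
  expect_equal(attr(lo, "co"), min(cos))
  expect_gt(attr(hi, "co"), attr(lo, "co"))
  expect_error(select_parents_by_co(list(), "high"), "empty")
})

test_that("circular permutation re-threads the chain and conserves contacts", {
  p <- compact_cuboid_path(c(2, 3, 3))
  n <- p$n

  cp0 <- circular_permute(p, 0)
  expect_identical(cp0$conf$coords, p$coords)

  expect_error(circular_permute(p, n), "in \\[0")
  expect_error(circular_permute(p, -1), "in \\[0")

  fam <- cp_family(p)
  expect_equal(nrow(fam), n)
  expect_equal(unique(fam$n_contacts), 16L)
  sigs <- vapply(fam$conf, function(cc) paste(t(cc$coords), collapse = ","),
                 character(1))
  expect_equal(length(unique(sigs)), n)  # all permutants distinct chains
  # identical point sets
  pset <- vapply(fam$conf, function(cc)
    paste(sort(apply(cc$coords, 1, paste, collapse = ",")), collapse = ";"),
    character(1))
  expect_equal(length(unique(pset)), 1L)
  expect_true(all(fam$co > 3 & fam$co < n - 1))
})

test_that("permutant contact maps equal the re-indexing oracle", {
  p <- collapse_homopolymer(18, c(2, 3, 3), seed = 11)
  n <- p$n
  parent_cm <- compute_contacts(p)
  for (k in c(1, 5, 9, 17)) {
    cp <- circular_permute(p, k)
    # oracle: re-index parent contacts, bond (k-1, k) <-> terminus contact
    prs <- as.matrix(parent_cm)
    prs <- prs[!(prs[, 1] == 0 & prs[, 2] == n - 1), , drop = FALSE]
    re <- t(apply(prs, 1, function(pr) sort((pr - k) %% n)))
    re <- rbind(re, c(0, n - 1))  # old bond k-1 -> k becomes this contact
    re <- re[order(re[, 1], re[, 2]), ]
    got <- as.matrix(compute_contacts(cp$conf))
    expect_equal(got, re, ignore_attr = TRUE)
  }
})

test_that("deterministic compact paths fill their boxes", {
  for (box in list(c(2, 2, 2), c(2, 3, 3), c(2, 3, 4), c(3, 4, 4))) {
    p <- compact_cuboid_path(box)
    expect_equal(nrow(compute_contacts(p)), cuboid_contact_count(box))
    expect_equal(sum((p$coords[1, ] - p$coords[p$n, ])^2), 1)
  }
  p27 <- compact_cuboid_path(c(3, 3, 3))
  expect_equal(nrow(compute_contacts(p27)), 28L)
  expect_false(inherits(p27, "parent_structure"))  # odd volume: no cycle
})

test_that("family manifests round-trip through the text formats", {
  fam <- cp_family(compact_cuboid_path(c(2, 2, 2)))
  dir <- withr::local_tempdir()
  manifest <- write_family(fam, dir)
  expect_equal(nrow(manifest), 8L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_conformation(file.path(dir, manifest$conformation_file[3]))
  expect_identical(back$coords, fam$conf[[3]]$coords)
  cm <- read_contact_map(file.path(dir, manifest$contacts_file[3]))
  expect_equal(nrow(cm), 5L)
})
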