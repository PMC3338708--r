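test_that("conformation validation reports every violation with indices", {
  rod <- cbind(0:3, 0L, 0L)
  expect_true(validate_conformation(rod)$ok)

  dup <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0, 0, 0))
  v <- validate_conformation(dup)
  expect_false(v$ok)
  expect_true(any(v$violations$type == "overlap" &
                    v$violations$i == 0 & v$violations$j == 4))

  gap <- rbind(c(0, 0, 0), c(2, 0, 0), c(3, 0, 0), c(4, 0, 0))
  v <- validate_conformation(gap)
  expect_false(v$ok)
  expect_true(any(v$violations$type == "bond_length" &
                    v$violations$i == 0 & v$violations$j == 1))

  expect_error(lattice_conformation(gap), "bond length")
})

test_that("contact maps match the brute-force pair scan on random coils", {
  for (s in 1:12) {
    n <- sample(c(8L, 16L, 32L, 48L), 1)
    conf <- random_coil(n, seed = 1000 + s)
    got <- compute_contacts(conf)
    want <- oracle_contacts(conf$coords)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(unname(as.matrix(got[, c("i", "j")])),
                   unname(want[order(want[, 1], want[, 2]), ,
                               drop = FALSE]),
                   ignore_attr = TRUE)
    }
    if (nrow(got)) {
      expect_true(all((got$j - got$i) %% 2 == 1))
      expect_true(all(got$j - got$i >= 3))
    }
  }
})

test_that("compact conformations have the edge-count contact number", {
  expect_equal(nrow(compute_contacts(compact_cuboid_path(c(2, 2, 2)))), 5L)
  expect_equal(nrow(compute_contacts(compact_cuboid_path(c(3, 4, 4)))), 57L)
  rod <- lattice_conformation(cbind(0:9, 0L, 0L))
  expect_equal(nrow(compute_contacts(rod)), 0L)
})

test_that("Go energy counts exactly the formed native contacts", {
  m <- toy8_model()
  expect_equal(go_energy(m$native, m), -5)
  expect_equal(fraction_native(m$native, m), 1)
  rod <- lattice_conformation(cbind(0:7, 0L, 0L))
  expect_equal(go_energy(rod, m), 0)
  expect_equal(fraction_native(rod, m), 0)

  m48 <- go_model(compact_cuboid_path(c(3, 4, 4)))
  expect_equal(go_energy(m48$native, m48), -57)

  # partial overlap on random coils: energy identity vs brute force
  for (s in 1:8) {
    conf <- random_coil(8, seed = 200 + s)
    formed <- oracle_contacts(conf$coords)
    nat <- as.matrix(m$contacts)
    shared <- sum(apply(formed, 1, function(p)
      any(nat[, 1] == p[1] & nat[, 2] == p[2])))
    expect_equal(go_energy(conf, m), -shared)
    expect_equal(go_energy(conf, m),
                 -m$epsilon * m$n_contacts * fraction_native(conf, m))
  }

  expect_error(go_energy(random_coil(10, 1), m), "mismatch")
})

test_that("epsilon scales the energy without changing the contact count", {
  m <- go_model(compact_cuboid_path(c(2, 2, 2)), epsilon = 2.5)
  expect_equal(go_energy(m$native, m), -12.5)
  expect_equal(fraction_native(m$native, m), 1)
})

test_that("contact order averages sequence separations", {
  expect_equal(contact_order(contact_map(rbind(c(0, 3)), 8)), 3)
  expect_equal(contact_order(contact_map(rbind(c(0, 3), c(2, 7)), 8)), 4)
  expect_error(contact_order(contact_map(matrix(integer(), ncol = 2), 8)),
               "empty")
})

test_that("conformation and contact-map files round-trip bit-exactly", {
  conf <- random_coil(20, seed = 9)
  conf$label <- "coil_A"
  path <- withr::local_tempfile(fileext = ".xyz")
  write_conformation(conf, path)
  back <- read_conformation(path)
  expect_identical(back$coords, conf$coords)
  expect_identical(back$label, "coil_A")

  cm <- compute_contacts(compact_cuboid_path(c(2, 3, 3)))
  cpath <- withr::local_tempfile(fileext = ".contacts")
  write_contact_map(cm, cpath)
  back_cm <- read_contact_map(cpath)
  expect_equal(as.matrix(back_cm), as.matrix(cm), ignore_attr = TRUE)
  expect_equal(attr(back_cm, "chain_length"), attr(cm, "chain_length"))

  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pseudo_pdb(conf, pdb)
  lines <- readLines(pdb)
  expect_length(grep("^ATOM", lines), 20L)
})
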