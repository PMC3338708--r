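# Independent oracles and small fixtures used across the suite.

# O(N^2) brute-force contact scan (independent of compute_contacts)
oracle_contacts <- function(coords) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      d <- coords[i, ] - coords[j, ]
      if (sum(d * d) == 1) out <- rbind(out, c(i - 1L, j - 1L))
    }
  }
  if (is.null(out)) matrix(integer(), ncol = 2) else out
}

# the 24 proper rotation matrices of the cube
proper_rotations_24 <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    for (sx in c(-1, 1)) for (sy in c(-1, 1)) for (sz in c(-1, 1)) {
      m <- matrix(0, 3, 3)
      m[1, p[1]] <- sx; m[2, p[2]] <- sy; m[3, p[3]] <- sz
      if (abs(det(m) - 1) < 1e-9) out[[length(out) + 1]] <- m
    }
  }
  out
}

# minimum RMSD over centroid alignment + the 24 lattice rotations
oracle_rmsd_24 <- function(a, b) {
  a <- scale(as.matrix(a), scale = FALSE)
  b <- scale(as.matrix(b), scale = FALSE)
  best <- Inf
  for (m in proper_rotations_24()) {
    d <- a %*% t(m) - b
    best <- min(best, sqrt(sum(d^2) / nrow(a)))
  }
  best
}

# recursive R enumeration of all N-bead SAWs from the origin with an energy
# histogram (independent of the C++ enumerator); feasible for N <= 7
oracle_enumerate_saw <- function(n, contacts = NULL) {
  key <- function(p) paste(p, collapse = ",")
  is_contact <- function(i, j) {
    if (abs(i - j) < 2) return(FALSE)
    if (is.null(contacts)) return(TRUE)
    any(contacts$i == min(i, j) - 1 & contacts$j == max(i, j) - 1)
  }
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  counts <- new.env()
  rec <- function(path, occ, e) {
    depth <- nrow(path)
    if (depth == n) {
      k <- as.character(e)
      counts[[k]] <- (if (is.null(counts[[k]])) 0 else counts[[k]]) + 1
      return(invisible())
    }
    for (d in seq_len(6)) {
      np <- path[depth, ] + dirs[d, ]
      if (!is.null(occ[[key(np)]])) next
      g <- 0
      for (dd in seq_len(6)) {
        nb <- occ[[key(np + dirs[dd, ])]]
        if (!is.null(nb) && is_contact(depth + 1, nb)) g <- g + 1
      }
      occ[[key(np)]] <- depth + 1
      rec(rbind(path, np), occ, e + g)
      rm(list = key(np), envir = occ)
    }
  }
  occ <- new.env()
  occ[[key(c(0, 0, 0))]] <- 1
  rec(matrix(0, 1, 3), occ, 0)
  out <- sapply(ls(counts), function(k) counts[[k]])
  names(out) <- ls(counts)
  out
}

# geometric enumeration of legal elementary moves at a bead, written from
# the move definitions (independent of the slot machinery in the engine)
oracle_moves <- function(coords, bead) {
  n <- nrow(coords)
  i <- bead + 1  # 1-based
  occ_key <- apply(coords, 1, paste, collapse = ",")
  occupied <- function(p) paste(p, collapse = ",") %in% occ_key
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  out <- list()
  add <- function(kind, beads0, nc) {
    out[[length(out) + 1]] <<- list(kind = kind, beads = beads0,
                                    new_coords = nc)
  }
  if (i == 1 || i == n) {
    a <- if (i == 1) 2 else n - 1
    for (d in seq_len(6)) {
      t1 <- coords[a, ] + dirs[d, ]
      if (!occupied(t1)) add("end-move", bead, matrix(t1, 1))
    }
  } else {
    v <- coords[i + 1, ] - coords[i - 1, ]
    if (sum(v * v) == 2) {
      t1 <- coords[i - 1, ] + coords[i + 1, ] - coords[i, ]
      if (!occupied(t1)) add("corner-flip", bead, matrix(t1, 1))
    }
    for (lo in c(i, i - 1)) {
      hi <- lo + 1
      if (lo < 2 || hi > n - 1) next
      u <- coords[hi + 1, ] - coords[lo - 1, ]
      if (sum(u * u) != 1) next
      if (!all(coords[hi, ] - coords[lo, ] == u)) next
      v0 <- coords[lo, ] - coords[lo - 1, ]
      cr <- c(u[2] * v0[3] - u[3] * v0[2], u[3] * v0[1] - u[1] * v0[3],
              u[1] * v0[2] - u[2] * v0[1])
      for (w in list(cr, -v0, -cr)) {
        t1 <- coords[lo - 1, ] + w
        t2 <- t1 + u
        occ_other <- setdiff(seq_len(n), c(lo, hi))
        free <- !any(apply(coords[occ_other, , drop = FALSE], 1,
                           function(p) all(p == t1) || all(p == t2)))
        if (free && lo == i) add("crankshaft", c(lo - 1, hi - 1),
                                 rbind(t1, t2))
        if (free && lo == i - 1) add("crankshaft", c(lo - 1, hi - 1),
                                     rbind(t1, t2))
      }
    }
  }
  out
}

# canonical string form of a move list for set comparison
move_set_signature <- function(moves) {
  sort(vapply(moves, function(m)
    paste(m$kind, paste(m$beads, collapse = ","),
          paste(t(m$new_coords), collapse = ","), sep = "|"),
    character(1)))
}

# batch-means standard error for a correlated series of indicators
batch_se <- function(x, n_batches = 50) {
  n <- length(x)
  bs <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
                  numeric(1))
  stats::sd(means) / sqrt(n_batches)
}

toy8_model <- function() go_model(compact_cuboid_path(c(2, 2, 2)))

# cached exact density of states of the 8-mer toy (counts by formed contacts)
toy8_dos <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- toy8_model()
      cache <<- latticefold:::cpp_enumerate_saw_energies(
        8L, as.matrix(m$contacts), FALSE)
    }
    cache
  }
})

# cached PT run + model for a small two-state permutant (N = 24)
toy24 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- collapse_homopolymer(24, c(2, 3, 4), seed = 5)
      m <- circular_permute(p, 4)$model
      ladder <- temperature_ladder(14, center = 0.63, span = c(0.75, 1.35))
      pt <- parallel_tempering(m, ladder, steps_per_round = 1000,
                               n_rounds = 6000, burnin_rounds = 1000,
                               seed = 3)
      cache <<- list(parent = p, model = m, pt = pt,
                     tm = melting_temperature(heat_capacity(pt)))
    }
    cache
  }
})

make_survival <- function(time, pu, n = 1e6) {
  out <- tibble::tibble(time = time, pu = pu, n_at_risk = round(pu * n))
  attr(out, "n") <- n
  attr(out, "n_censored") <- 0L
  class(out) <- c("survival_curve", class(out))
  out
}

make_profile <- function(energy, f, temperature = 1) {
  out <- tibble::tibble(energy = energy, free_energy = f)
  attr(out, "temperature") <- temperature
  class(out) <- c("fe_profile", class(out))
  out
}
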