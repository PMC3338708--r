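#' Expected contact count of a maximally compact cuboid
#'
#' A Hamiltonian path filling an `a x b x c` cuboid has
#' `(a-1)bc + a(b-1)c + ab(c-1)` lattice edges among its sites, of which
#' `abc - 1` are chain bonds; the rest are non-bonded contacts.  For the
#' 3 x 4 x 4 cuboid this is 104 - 47 = 57.
#'
#' @param box Integer vector of three cuboid dimensions.
#' @return Integer: non-bonded contacts of any compact conformation.
#' @export
cuboid_contact_count <- function(box) {
  box <- as.integer(box)
  stopifnot(length(box) == 3L, all(box >= 1L))
  edges <- (box[1] - 1L) * box[2] * box[3] + box[1] * (box[2] - 1L) * box[3] +
    box[1] * box[2] * (box[3] - 1L)
  edges - (prod(box) - 1L)
}

#' Parent structure: a maximally compact conformation with adjacent termini
#'
#' A parent occupies every site of its cuboid box (a Hamiltonian path) and,
#' so that circular permutation is defined, its first and last beads sit on
#' neighbouring lattice sites.
#'
#' @param conf A `lattice_conf`.
#' @param box Cuboid dimensions; `prod(box)` must equal the chain length.
#' @param label Optional label.
#' @param require_termini Require terminus adjacency (default `TRUE`).
#' @return A `parent_structure` (subclass of `lattice_conf`) with fields
#'   `box` and `label`.
#' @export
parent_structure <- function(conf, box, label = NULL, require_termini = TRUE) {
  if (!inherits(conf, "lattice_conf")) conf <- lattice_conformation(conf)
  box <- sort(as.integer(box))
  if (prod(box) != conf$n)
    rlang::abort("box volume must equal the chain length")
  xyz <- sweep(conf$coords, 2L, apply(conf$coords, 2L, min))
  ext <- sort(apply(xyz, 2L, max) + 1L)
  if (!all(ext == box))
    rlang::abort("conformation does not fill the stated box")
  if (require_termini && !termini_adjacent(conf))
    rlang::abort("parent termini are not at adjacent lattice sites")
  structure(list(coords = conf$coords, n = conf$n,
                 label = label %||% conf$label, box = box),
            class = c("parent_structure", "lattice_conf"))
}

termini_adjacent <- function(conf) {
  d <- conf$coords[1L, ] - conf$coords[conf$n, ]
  sum(d * d) == 1L
}

#' @export
print.parent_structure <- function(x, ...) {
  cat(sprintf("<parent_structure> N = %d, box %s, %d contacts%s\n", x$n,
              paste(x$box, collapse = "x"), cuboid_contact_count(x$box),
              if (!is.null(x$label)) paste0("  label: ", x$label) else ""))
  invisible(x)
}

# Sites of a cuboid in boustrophedon order: consecutive sites are adjacent.
serpentine_sites <- function(box) {
  box <- as.integer(box)
  out <- matrix(0L, nrow = prod(box), ncol = 3L)
  r <- 1L
  row_idx <- 0L
  for (z in 0:(box[3] - 1L)) {
    ys <- if (z %% 2L == 0L) 0:(box[2] - 1L) else (box[2] - 1L):0
    for (y in ys) {
      xs <- if (row_idx %% 2L == 0L) 0:(box[1] - 1L) else (box[1] - 1L):0
      for (x in xs) {
        out[r, ] <- c(x, y, z)
        r <- r + 1L
      }
      row_idx <- row_idx + 1L
    }
  }
  out
}

# Hamiltonian cycle through an a x b x c cuboid with even volume: a
# Hamiltonian cycle on one even-sized face is traversed column-by-column
# along the remaining axis, alternating direction, which closes back on the
# starting site.
cuboid_hamiltonian_cycle <- function(box) {
  box <- as.integer(box)
  if (prod(box) %% 2L != 0L)
    rlang::abort("a Hamiltonian cycle requires an even number of sites")
  # choose the column axis `a` so the face b x c has an even dimension to
  # serve as the comb's column direction
  perm <- NULL
  for (p in list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                 c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))) {
    d <- box[p]
    if (d[2] %% 2L == 0L && d[2] >= 2L && d[3] >= 2L) {
      perm <- p
      break
    }
  }
  if (is.null(perm))
    rlang::abort("no face of the box supports the comb construction")
  d <- box[perm]  # a = d[1] columns of height a along axis perm[1]
  m <- d[2]       # even comb dimension
  n <- d[3]
  # 2D comb cycle on m x n (m even): up each column for v >= 1, return along
  # v = 0.
  face <- matrix(0L, nrow = m * n, ncol = 2L)
  r <- 1L
  for (u in 0:(m - 1L)) {
    vs <- if (u %% 2L == 0L) 1:(n - 1L) else (n - 1L):1
    for (v in vs) {
      face[r, ] <- c(u, v)
      r <- r + 1L
    }
  }
  for (u in (m - 1L):0) {
    face[r, ] <- c(u, 0L)
    r <- r + 1L
  }
  ncol_face <- nrow(face)  # even since m * n even
  coords <- matrix(0L, nrow = prod(box), ncol = 3L)
  r <- 1L
  for (ci in seq_len(ncol_face)) {
    hs <- if (ci %% 2L == 1L) 0:(d[1] - 1L) else (d[1] - 1L):0
    for (h in hs) {
      coords[r, perm] <- c(h, face[ci, 1L], face[ci, 2L])
      r <- r + 1L
    }
  }
  coords
}

#' Deterministic maximally compact conformation
#'
#' Explicit construction of a Hamiltonian path filling the box.  For boxes
#' with an even number of sites the path is a Hamiltonian cycle minus one
#' edge, so its termini are adjacent and it can seed a circular-permutant
#' family; odd-volume boxes (such as 3 x 3 x 3) cannot have adjacent termini
#' on a bipartite lattice and a serpentine path is returned instead.
#'
#' @param box Integer vector of three cuboid dimensions (volume >= 8).
#' @param label Optional label.
#' @return A `parent_structure` (even volume) or plain `lattice_conf` (odd).
#' @examples
#' nrow(compute_contacts(compact_cuboid_path(c(3, 4, 4)))) # 57
#' @export
compact_cuboid_path <- function(box, label = NULL) {
  box <- sort(as.integer(box))
  stopifnot(length(box) == 3L, prod(box) >= 8L)
  if (prod(box) %% 2L == 0L) {
    coords <- cuboid_hamiltonian_cycle(box)
    parent_structure(lattice_conformation(coords), box, label = label)
  } else {
    conf <- lattice_conformation(serpentine_sites(box), label = label)
    conf
  }
}

#' Default annealing schedule for homopolymer collapse
#'
#' @param t_hi,t_lo Initial and final annealing temperatures (reduced units).
#' @param n_stages Number of geometric cooling stages.
#' @param steps_per_stage MC steps per stage.
#' @param t_search Temperature of the post-anneal search phase in which the
#'   chain keeps rearranging until a maximally compact state with adjacent
#'   termini is visited.
#' @param search_steps MC step budget of the search phase.
#' @param termini_weight Extra weight of the terminus-terminus contact in
#'   the collapse energy.  The pair (first, last bead) is itself a
#'   non-bonded pair, so up-weighting it makes compact states with adjacent
#'   termini the annealing ground states without touching any other term;
#'   all such states keep equal energy, and the bias plays no role in the
#'   Go-model simulations that follow.
#' @return A list of schedule parameters.
#' @export
collapse_schedule <- function(t_hi = 2.0, t_lo = 0.3, n_stages = 30L,
                              steps_per_stage = 2e5, t_search = 0.5,
                              search_steps = 2e7, termini_weight = 4L) {
  list(t_hi = t_hi, t_lo = t_lo, n_stages = as.integer(n_stages),
       steps_per_stage = steps_per_stage, t_search = t_search,
       search_steps = search_steps,
       termini_weight = as.integer(termini_weight))
}

#' Generate a maximally compact parent by homopolymer collapse
#'
#' Simulated-annealing Monte Carlo of a homopolymer whose energy is -1 per
#' non-bonded contact, confined to a box one lattice unit larger than the
#' target cuboid along its shortest side (the target cuboid is the unique
#' maximum-contact shape inside that confinement).  After cooling, a
#' fixed-temperature search phase waits for a ground-state visit whose
#' termini are adjacent.  Each attempt is deterministic given the seed;
#' failed attempts are retried with derived seeds.
#'
#' @param n Chain length; must equal `prod(box)`.
#' @param box Target cuboid dimensions.
#' @param seed Integer seed.
#' @param schedule A [collapse_schedule()].
#' @param max_attempts Retry budget.
#' @param label Optional label (default derived from the seed).
#' @return A `parent_structure` with attribute `attempts` (per-attempt step
#'   counts).
#' @examples
#' p <- collapse_homopolymer(8, c(2, 2, 2), seed = 1)
#' nrow(compute_contacts(p)) # 5
#' @export
collapse_homopolymer <- function(n, box, seed, schedule = collapse_schedule(),
                                 max_attempts = 25L, label = NULL) {
  box <- sort(as.integer(box))
  if (prod(box) != n) rlang::abort("box volume must equal chain length n")
  if (n < 8L) rlang::abort("collapse requires n >= 8")
  # confine to the target cuboid extended by one layer along its longest
  # side: the target cuboid is then the unique maximum-contact shape inside
  # the confinement (expanding a short side admits degenerate competitors)
  confine <- box
  confine[3L] <- confine[3L] + 1L
  target <- cuboid_contact_count(box)
  start <- serpentine_sites(confine)[seq_len(n), , drop = FALSE]
  temps <- exp(seq(log(schedule$t_hi), log(schedule$t_lo),
                   length.out = schedule$n_stages))
  stats <- numeric(0)
  for (attempt in seq_len(max_attempts)) {
    res <- cpp_collapse(start, confine, box, temps,
                        schedule$steps_per_stage, target, schedule$t_search,
                        schedule$search_steps, child_seed(seed, attempt),
                        schedule$termini_weight %||% 1L)
    stats <- c(stats, res$steps_used)
    if (isTRUE(res$success)) {
      conf <- canonicalize_box(res$coords, box)
      out <- parent_structure(lattice_conformation(conf), box,
                              label = label %||% sprintf("collapse_s%d", seed))
      attr(out, "attempts") <- stats
      return(out)
    }
  }
  rlang::abort(sprintf(
    "homopolymer collapse failed after %d attempts (%.3g MC steps total)",
    max_attempts, sum(stats)))
}

# rotate/permute axes so the bounding extents match the requested box order
canonicalize_box <- function(coords, box) {
  coords <- sweep(coords, 2L, apply(coords, 2L, min))
  ext <- apply(coords, 2L, max) + 1L
  perm <- order(ext)
  coords <- coords[, perm, drop = FALSE]
  storage.mode(coords) <- "integer"
  coords
}

#' Pool of collapsed parent candidates
#'
#' @param n_candidates Number of seeded collapse runs.
#' @param n Chain length.
#' @param box Target cuboid.
#' @param seed Master seed; run `i` uses a derived seed.
#' @param schedule A [collapse_schedule()].
#' @return Tibble with columns `label`, `seed`, `co` and a list-column
#'   `parent` of `parent_structure` objects.
#' @export
generate_parent_pool <- function(n_candidates = 200L, n = 48L,
                                 box = c(3L, 4L, 4L), seed = 1L,
                                 schedule = collapse_schedule()) {
  purrr::map_dfr(seq_len(n_candidates), function(i) {
    p <- collapse_homopolymer(n, box, seed = child_seed(seed, i),
                              schedule = schedule,
                              label = sprintf("cand%03d", i))
    tibble::tibble(label = p$label, seed = child_seed(seed, i),
                   co = contact_order(compute_contacts(p)), parent = list(p))
  })
}

#' Select the extreme-contact-order parent from a candidate pool
#'
#' @param candidates A list of `parent_structure`s, or the tibble returned by
#'   [generate_parent_pool()].
#' @param mode `"high"` or `"low"`: maximal or minimal contact order.  Ties
#'   are broken by lexicographic coordinate order.
#' @return The selected `parent_structure`, with its contact order in
#'   `attr(, "co")`.
#' @export
select_parents_by_co <- function(candidates, mode = c("high", "low")) {
  mode <- match.arg(mode)
  if (is.data.frame(candidates)) candidates <- candidates$parent
  if (!length(candidates)) rlang::abort("empty candidate list")
  cos <- vapply(candidates, function(p) contact_order(compute_contacts(p)),
                numeric(1))
  best <- if (mode == "high") max(cos) else min(cos)
  idx <- which(abs(cos - best) < 1e-12)
  if (length(idx) > 1L) {
    keys <- vapply(candidates[idx],
                   function(p) paste(t(p$coords), collapse = ","),
                   character(1))
    idx <- idx[order(keys)][1L]
  }
  out <- candidates[[idx]]
  attr(out, "co") <- cos[idx]
  out
}

#' Circular permutation of a parent structure
#'
#' Permutant `k` re-threads the chain through the same point set: bead `j`
#' of the permutant is bead `(j + k) mod N` of the parent.  The parent's
#' terminus-terminus contact becomes the new chain bond and the old bond
#' between beads `k - 1` and `k` becomes a non-bonded contact, so the
#' number of native contacts is conserved.
#'
#' @param parent A `parent_structure` (termini must be adjacent).
#' @param k Cut index in `0:(N - 1)`; `k = 0` returns the parent itself.
#' @param epsilon Interaction energy for the permutant's Go model.
#' @return A list with `conf` (the re-threaded `lattice_conf`) and `model`
#'   (its [go_model()]).
#' @export
circular_permute <- function(parent, k, epsilon = 1) {
  if (!inherits(parent, "parent_structure"))
    rlang::abort("parent must be a parent_structure")
  if (!termini_adjacent(parent))
    rlang::abort("parent termini are not adjacent")
  n <- parent$n
  if (length(k) != 1L || k != round(k) || k < 0 || k >= n)
    rlang::abort(sprintf("k must be an integer in [0, %d)", n))
  idx <- ((seq_len(n) - 1L + k) %% n) + 1L
  lab <- sprintf("%s_cp%02d", parent$label %||% "parent", k)
  conf <- lattice_conformation(parent$coords[idx, , drop = FALSE], label = lab)
  list(conf = conf, model = go_model(conf, epsilon = epsilon, label = lab))
}

#' Family of all circular permutants of a parent
#'
#' @param parent A `parent_structure`.
#' @param epsilon Interaction energy.
#' @return A `cp_family` tibble with one row per permutant `k = 0:(N-1)`:
#'   `label`, `k`, `co`, `n_contacts`, and list-columns `conf`, `model`.
#' @export
cp_family <- function(parent, epsilon = 1) {
  n <- parent$n
  rows <- purrr::map(0:(n - 1L), function(k) {
    cp <- circular_permute(parent, k, epsilon = epsilon)
    tibble::tibble(label = cp$conf$label, k = k,
                   co = contact_order(cp$model$contacts),
                   n_contacts = cp$model$n_contacts,
                   conf = list(cp$conf), model = list(cp$model))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "parent") <- parent
  class(out) <- c("cp_family", class(out))
  out
}

#' Write a family manifest and its conformations to a directory
#'
#' Writes one conformation file and one contact-map file per permutant plus
#' a `manifest.csv` with columns `label`, `k`, `co`, `n_contacts`,
#' `conformation_file`, `contacts_file`.
#'
#' @param family A [cp_family()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_family <- function(family, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- dplyr::mutate(
    tibble::as_tibble(family[c("label", "k", "co", "n_contacts")]),
    conformation_file = sprintf("%s.xyz", .data$label),
    contacts_file = sprintf("%s.contacts", .data$label))
  purrr::pwalk(list(family$conf, family$model, manifest$conformation_file,
                    manifest$contacts_file), function(conf, model, cf, mf) {
    write_conformation(conf, file.path(dir, cf))
    write_contact_map(model$contacts, file.path(dir, mf))
  })
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# deterministic 31-bit child seeds from a master seed
child_seed <- function(seed, ...) {
  x <- as.numeric(seed)
  for (k in c(...)) {
    x <- (x * 69069 + as.numeric(k) * 2654435761 + 1013904223) %% 2147483647
  }
  as.integer(floor(x)) + 1L
}
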