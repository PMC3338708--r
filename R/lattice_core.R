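#' Lattice conformations
#'
#' A lattice conformation is an ordered chain of `N` beads on the simple
#' cubic lattice: consecutive beads sit at unit distance (the bond length is
#' one lattice spacing) and no two beads share a site.
#'
#' @param coords Integer matrix with one row per bead and columns x, y, z.
#' @param label Optional character label.
#' @param validate Check the chain invariants (default `TRUE`).
#' @return An object of class `lattice_conf`: a list with elements `coords`
#'   (integer matrix), `n` (chain length) and `label`.
#' @examples
#' rod <- lattice_conformation(cbind(0:3, 0, 0))
#' rod$n
#' @export
lattice_conformation <- function(coords, label = NULL, validate = TRUE) {
  coords <- as_coord_matrix(coords)
  if (validate) {
    v <- validate_conformation(coords)
    if (!v$ok) {
      msg <- paste(utils::head(format_violations(v$violations), 5L),
                   collapse = "; ")
      rlang::abort(paste0("invalid lattice conformation: ", msg))
    }
  }
  structure(list(coords = coords, n = nrow(coords), label = label),
            class = "lattice_conf")
}

as_coord_matrix <- function(coords) {
  if (inherits(coords, "lattice_conf")) return(coords$coords)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) rlang::abort("coords must have three columns (x, y, z)")
  if (nrow(coords) < 1L) rlang::abort("coords must be non-empty")
  if (any(!is.finite(coords)) || any(coords != round(coords)))
    rlang::abort("coords must be finite integers")
  storage.mode(coords) <- "integer"
  dimnames(coords) <- NULL
  coords
}

#' Validate a chain of lattice coordinates
#'
#' Diagnostic check of the chain invariants: unit bond lengths between
#' consecutive beads and full self-avoidance.  All violations are reported
#' with the offending (0-based) bead indices rather than only the first.
#'
#' @param coords Integer matrix of bead coordinates, or a `lattice_conf`.
#' @return A list with `ok` (logical) and `violations`, a tibble with columns
#'   `type` (`"bond_length"` or `"overlap"`), `i` and `j`.
#' @examples
#' validate_conformation(cbind(0:3, 0, 0))$ok
#' @export
validate_conformation <- function(coords) {
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  viol <- list()
  if (n >= 2L) {
    d2 <- rowSums((coords[-1L, , drop = FALSE] -
                   coords[-n, , drop = FALSE])^2)
    bad <- which(d2 != 1L)
    if (length(bad))
      viol$bond <- tibble::tibble(type = "bond_length", i = bad - 1L, j = bad)
  }
  key <- paste(coords[, 1L], coords[, 2L], coords[, 3L])
  dup <- which(duplicated(key))
  if (length(dup)) {
    first <- match(key[dup], key)
    viol$overlap <- tibble::tibble(type = "overlap", i = first - 1L,
                                   j = dup - 1L)
  }
  if (n < 4L)
    viol$short <- tibble::tibble(type = "chain_too_short", i = n, j = NA_integer_)
  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble::tibble(type = character(), i = integer(), j = integer())
  list(ok = nrow(violations) == 0L, violations = violations)
}

format_violations <- function(v) {
  dplyr::case_when(
    v$type == "overlap" ~ sprintf("overlap at indices (%d, %d)", v$i, v$j),
    v$type == "chain_too_short" ~ sprintf("chain length %d < 4", v$i),
    TRUE ~ sprintf("bond length != 1 at (%d, %d)", v$i, v$j))
}

#' @export
print.lattice_conf <- function(x, ...) {
  cat(sprintf("<lattice_conf> N = %d%s\n", x$n,
              if (!is.null(x$label)) paste0("  label: ", x$label) else ""))
  invisible(x)
}

#' Non-bonded contact map of a conformation
#'
#' A non-bonded contact is a pair of beads `(i, j)` with `j > i + 1` that
#' occupy neighbouring lattice sites.  On the cubic lattice beads at unit
#' distance have opposite coordinate-sum parity, so every contact has odd
#' sequence separation `j - i >= 3`.
#'
#' @param conf A `lattice_conf` (or coordinate matrix).
#' @return A `contact_map`: a tibble with 0-based integer columns `i < j`,
#'   sorted lexicographically, carrying the chain length in
#'   `attr(, "chain_length")`.
#' @examples
#' cube <- compact_cuboid_path(c(2, 2, 2))
#' nrow(compute_contacts(cube)) # 5
#' @export
compute_contacts <- function(conf) {
  coords <- as_coord_matrix(conf)
  v <- validate_conformation(coords)
  if (!v$ok)
    rlang::abort(paste0("invalid conformation: ",
                        paste(format_violations(v$violations), collapse = "; ")))
  n <- nrow(coords)
  d2 <- as.matrix(stats::dist(coords, method = "euclidean"))^2
  sep <- abs(row(d2) - col(d2))
  hit <- which(abs(d2 - 1) < 1e-9 & sep > 1L & upper.tri(d2), arr.ind = TRUE)
  contact_map(cbind(hit[, 1L] - 1L, hit[, 2L] - 1L), n)
}

#' Construct a contact map from index pairs
#'
#' @param pairs Two-column integer matrix of 0-based pairs `i < j`.
#' @param chain_length Chain length `N`.
#' @return A `contact_map` tibble with columns `i`, `j`.
#' @export
contact_map <- function(pairs, chain_length) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs)) {
    ij <- cbind(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
    if (any(ij[, 2L] - ij[, 1L] < 2L))
      rlang::abort("contact pairs must satisfy j > i + 1")
    if (any(ij < 0L) || any(ij >= chain_length))
      rlang::abort("contact indices out of [0, N)")
    ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
    if (anyDuplicated(paste(ij[, 1L], ij[, 2L])))
      rlang::abort("duplicated contact pair")
  } else {
    ij <- matrix(integer(), ncol = 2L)
  }
  out <- tibble::tibble(i = as.integer(ij[, 1L]), j = as.integer(ij[, 2L]))
  attr(out, "chain_length") <- as.integer(chain_length)
  class(out) <- c("contact_map", class(out))
  out
}

#' Go model of a native structure
#'
#' The Gō (native-centric) potential assigns energy `-epsilon` to every
#' native non-bonded contact that is formed and zero to everything else, so a
#' conformation's energy is `-epsilon` times the number of native contacts it
#' shares with the native structure.  Non-native adjacencies are neutral.
#'
#' @param native A `lattice_conf`: the native structure.
#' @param epsilon Uniform interaction energy in reduced units (default 1).
#' @param label Optional label.
#' @return An object of class `go_model` with elements `native`, `contacts`
#'   (a `contact_map`), `epsilon`, `n` and `n_contacts`.
#' @examples
#' m <- go_model(compact_cuboid_path(c(2, 2, 2)))
#' m$n_contacts # 5
#' @export
go_model <- function(native, epsilon = 1, label = NULL) {
  if (!inherits(native, "lattice_conf"))
    native <- lattice_conformation(native)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    rlang::abort("epsilon must be a single positive number")
  contacts <- compute_contacts(native)
  structure(list(native = native, contacts = contacts, epsilon = epsilon,
                 n = native$n, n_contacts = nrow(contacts),
                 label = label %||% native$label),
            class = "go_model")
}

#' @export
print.go_model <- function(x, ...) {
  cat(sprintf("<go_model> N = %d, %d native contacts, epsilon = %g%s\n",
              x$n, x$n_contacts, x$epsilon,
              if (!is.null(x$label)) paste0("  label: ", x$label) else ""))
  invisible(x)
}

contact_key <- function(cmap) paste(cmap$i, cmap$j)

#' Go energy of a conformation
#'
#' @param conf A `lattice_conf` with the model's chain length.
#' @param model A [go_model()].
#' @return Energy in reduced units: `-epsilon` times the number of formed
#'   native contacts (an integer multiple of `-epsilon`).
#' @export
go_energy <- function(conf, model) {
  -model$epsilon * n_formed_native(conf, model)
}

n_formed_native <- function(conf, model) {
  if (!inherits(conf, "lattice_conf")) conf <- lattice_conformation(conf)
  if (conf$n != model$n)
    rlang::abort(sprintf("chain length mismatch: conformation %d, model %d",
                         conf$n, model$n))
  formed <- compute_contacts(conf)
  sum(contact_key(formed) %in% contact_key(model$contacts))
}

#' Fraction of native contacts
#'
#' @inheritParams go_energy
#' @return `Q` in `[0, 1]`: formed native contacts over total native
#'   contacts.  `Q = 1` exactly when the energy equals
#'   `-epsilon * n_contacts`.
#' @export
fraction_native <- function(conf, model) {
  n_formed_native(conf, model) / model$n_contacts
}

#' Absolute contact order
#'
#' The contact order of a contact map is the mean sequence separation
#' `j - i` over its contacts.  With the chain length fixed across a family
#' of circular permutants the absolute and relative (length-normalised)
#' versions rank structures identically, so the absolute value is reported.
#'
#' @param cmap A `contact_map` (or a `lattice_conf`/`go_model`, whose
#'   contacts are used).
#' @return The contact order, in sequence-separation units.
#' @examples
#' contact_order(contact_map(rbind(c(0, 3), c(2, 7)), 8)) # 4
#' @export
contact_order <- function(cmap) {
  if (inherits(cmap, "go_model")) cmap <- cmap$contacts
  if (inherits(cmap, "lattice_conf")) cmap <- compute_contacts(cmap)
  if (nrow(cmap) == 0L) rlang::abort("contact order of an empty contact map is undefined")
  mean(cmap$j - cmap$i)
}

# ---- plain-text serialization ----------------------------------------------

#' Read and write lattice conformations as plain text
#'
#' One line `"x y z"` per bead in chain order; `#`-prefixed header lines
#' carry the chain length and an optional label.  Round-trips bit-exactly.
#'
#' @param conf A `lattice_conf`.
#' @param path File path.
#' @return `write_conformation()` returns `path` invisibly;
#'   `read_conformation()` returns a `lattice_conf`.
#' @export
write_conformation <- function(conf, path) {
  stopifnot(inherits(conf, "lattice_conf"))
  hdr <- c(sprintf("# N %d", conf$n),
           if (!is.null(conf$label)) sprintf("# label %s", conf$label))
  body <- apply(conf$coords, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_conformation
#' @export
read_conformation <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(trimws(body))]
  coords <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.integer))
  label <- NULL
  lab_line <- grep("^# label ", hdr, value = TRUE)
  if (length(lab_line)) label <- sub("^# label ", "", lab_line[1L])
  n_line <- grep("^# N ", hdr, value = TRUE)
  if (length(n_line) && as.integer(sub("^# N ", "", n_line[1L])) != nrow(coords))
    rlang::abort("header chain length does not match number of coordinate lines")
  lattice_conformation(coords, label = label)
}

#' Read and write contact maps as plain text
#'
#' One `"i j"` pair per line, 0-based, sorted lexicographically; a header
#' line carries the chain length.
#'
#' @param cmap A `contact_map`.
#' @param path File path.
#' @export
write_contact_map <- function(cmap, path) {
  writeLines(c(sprintf("# N %d", attr(cmap, "chain_length")),
               sprintf("%d %d", cmap$i, cmap$j)), path)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  lines <- readLines(path)
  n_line <- grep("^# N ", lines, value = TRUE)
  if (!length(n_line)) rlang::abort("contact map file lacks a '# N' header")
  n <- as.integer(sub("^# N ", "", n_line[1L]))
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(trimws(body))]
  if (!length(body)) return(contact_map(matrix(integer(), ncol = 2L), n))
  pairs <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.integer))
  contact_map(pairs, n)
}

#' Export a conformation as a CA-only pseudo-PDB
#'
#' Coordinates are scaled by a pseudo bond length (3.8 Angstrom by default,
#' the CA-CA virtual bond) for viewing in molecular graphics programs.
#'
#' @param conf A `lattice_conf`.
#' @param path Output path.
#' @param scale Angstroms per lattice unit.
#' @export
write_pseudo_pdb <- function(conf, path, scale = 3.8) {
  stopifnot(inherits(conf, "lattice_conf"))
  xyz <- conf$coords * scale
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(conf$n), seq_len(conf$n), xyz[, 1L], xyz[, 2L], xyz[, 3L])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
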