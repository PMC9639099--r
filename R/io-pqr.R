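#' Read a PQR point-charge structure
#'
#' Parses whitespace-delimited ATOM/HETATM records carrying per-atom partial
#' charge (e) and van der Waals radius (Angstrom). Both common dialects are
#' accepted and auto-detected per line: 11 fields (with a chain identifier)
#' and 10 fields (without); records lacking a chain get `chain = NA`.
#'
#' @param path Path to a PQR file.
#' @param label Structure label; defaults to the file name.
#' @return A [as_structure()] tibble, atom order as in the file.
#' @seealso [write_pqr()]
#' @examples
#' f <- tempfile(fileext = ".pqr")
#' writeLines("ATOM 1 FE CLU A 500 0.0 0.0 5.0 1.0 1.5", f)
#' read_pqr(f)
#' @export
read_pqr <- function(path, label = basename(path)) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM|HETATM)\\b", lines)
  idx <- which(is_atom)
  if (length(idx) == 0) abort(paste0("no ATOM/HETATM records in ", path))

  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!length(f) %in% c(10L, 11L)) {
      abort(sprintf("malformed PQR record at line %d: expected 10 or 11 fields, got %d",
                    i, length(f)))
    }
    has_chain <- length(f) == 11L
    num_idx <- if (has_chain) 6:11 else 5:10
    nums <- suppressWarnings(as.numeric(f[num_idx]))
    if (anyNA(nums)) {
      abort(sprintf("malformed PQR record at line %d: non-numeric field '%s'",
                    i, f[num_idx][which(is.na(nums))[1]]))
    }
    serial <- suppressWarnings(as.integer(f[2]))
    if (is.na(serial)) {
      abort(sprintf("malformed PQR record at line %d: bad serial '%s'", i, f[2]))
    }
    rows[[k]] <- tibble(
      serial = serial, name = f[3], residue_name = f[4],
      chain = if (has_chain) f[5] else NA_character_,
      residue_seq = as.integer(nums[1]),
      x = nums[2], y = nums[3], z = nums[4],
      charge = nums[5], radius = nums[6])
  }
  as_structure(dplyr::bind_rows(rows), label = label)
}

#' Write a structure to PQR
#'
#' Emits whitespace-delimited ATOM records, numeric fields to 4 decimals,
#' re-readable by [read_pqr()]. Atoms with `chain = NA` are written in the
#' 10-field chainless dialect.
#'
#' @param structure A structure tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(structure, path) {
  structure <- as_structure(structure,
                            label = attr(structure, "label") %||% "structure",
                            et_entry_serial = attr(structure, "et_entry_serial"))
  lines <- purrr::pmap_chr(structure, function(serial, name, residue_name,
                                               chain, residue_seq,
                                               x, y, z, charge, radius) {
    if (is.na(chain)) {
      sprintf("ATOM %6d %-4s %-4s %5d %10.4f %10.4f %10.4f %9.4f %8.4f",
              serial, name, residue_name, residue_seq, x, y, z, charge, radius)
    } else {
      sprintf("ATOM %6d %-4s %-4s %s %5d %10.4f %10.4f %10.4f %9.4f %8.4f",
              serial, name, residue_name, chain, residue_seq,
              x, y, z, charge, radius)
    }
  })
  ok <- tryCatch(suppressWarnings({ writeLines(lines, path); TRUE }),
                 error = function(e) FALSE)
  if (!ok) abort(paste0("cannot write PQR to ", path))
  invisible(path)
}

#' Net charge of a structure
#'
#' Sum of atomic partial charges, in e. Invariant under any rigid motion.
#'
#' @param structure A structure tibble.
#' @return Net charge, e.
#' @export
net_charge <- function(structure) sum(structure$charge)

#' Dipole moment about the center of charge
#'
#' For a molecule with nonzero net charge the dipole depends on the pole;
#' it is evaluated about the center of charge with absolute-value weights,
#' `sum(|q_i| r_i) / sum(|q_i|)`. (Weighting by signed charges would make
#' the dipole about that pole vanish identically for any charged molecule,
#' since `sum(q_i (r_i - sum(q_j r_j)/Q)) = 0` by construction.) When the
#' structure carries essentially no charge (`sum |q| <= 1e-6` e) the
#' unweighted centroid is used. The modulus is reported both in e*Angstrom
#' and debye (1 e*Angstrom = 4.803 D).
#'
#' @param structure A structure tibble.
#' @return One-row tibble: `mu_x`, `mu_y`, `mu_z`, `modulus_eA`,
#'   `modulus_debye`, `pole_x`, `pole_y`, `pole_z`.
#' @export
dipole_moment <- function(structure) {
  q <- structure$charge
  xyz <- coords(structure)
  W <- sum(abs(q))
  pole <- if (W > 1e-6) colSums(abs(q) * xyz) / W else colMeans(xyz)
  mu <- colSums(q * sweep(xyz, 2, pole))
  mod <- sqrt(sum(mu^2))
  tibble(mu_x = mu[1], mu_y = mu[2], mu_z = mu[3],
         modulus_eA = mod,
         modulus_debye = mod * .const$eA_to_debye,
         pole_x = pole[1], pole_y = pole[2], pole_z = pole[3])
}

#' Mark the electron-transfer entry atom
#'
#' Sets the ET-entry atom — for the modelled hydrogenase, the iron of the
#' distal iron-sulfur cluster, the electron entry/exit site whose distance
#' to the electrode gates the transfer rate. The selector is either
#' `"serial=N"` or `"chain:resname:resseq:atomname"` where any component may
#' be the wildcard `*`.
#'
#' @param structure A structure tibble.
#' @param selector Selector string; must match exactly one atom.
#' @return The structure with its ET-entry attribute set.
#' @examples
#' s <- toy_protein(n_atoms = 20, seed = 1)
#' mark_entry_atom(s, "serial=1")
#' @export
mark_entry_atom <- function(structure, selector) {
  hit <- if (grepl("^serial\\s*=", selector)) {
    n <- as.integer(sub("^serial\\s*=\\s*", "", selector))
    which(structure$serial == n)
  } else {
    parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
    if (length(parts) != 4) {
      abort("selector must be 'serial=N' or 'chain:resname:resseq:atomname'")
    }
    match_part <- function(value, pattern) {
      pattern == "*" | is.na(value) & pattern == "NA" |
        !is.na(value) & as.character(value) == pattern
    }
    which(match_part(structure$chain, parts[1]) &
          match_part(structure$residue_name, parts[2]) &
          match_part(structure$residue_seq, parts[3]) &
          match_part(structure$name, parts[4]))
  }
  if (length(hit) == 0) {
    abort(paste0("selector '", selector, "' matches no atom"))
  }
  if (length(hit) > 1) {
    cand <- structure[hit, c("serial", "name", "residue_name", "residue_seq")]
    abort(paste0("selector '", selector, "' is ambiguous; candidates: ",
                 paste(sprintf("serial %d (%s %s %d)", cand$serial, cand$name,
                               cand$residue_name, cand$residue_seq),
                       collapse = "; ")))
  }
  as_structure(structure, label = attr(structure, "label") %||% "structure",
               et_entry_serial = structure$serial[hit])
}
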