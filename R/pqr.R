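#' Read per-atom charges from a PQR file
#'
#' Parses the whitespace-separated PQR dialect: `ATOM`/`HETATM` records with
#' fields serial, atom name, residue name, optional chain ID, residue
#' number, x, y, z (angstrom), charge (e), radius (angstrom). All other
#' lines (REMARK, TER, END, ...) are ignored. Coordinates and radii are
#' converted to nm on read.
#'
#' @param path Path to a PQR file, or a character vector of lines.
#' @return A data frame of atom records with columns `name`, `x`, `y`, `z`
#'   (nm), `charge` (e), `radius` (nm), in file order.
#' @export
read_pqr <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    as.character(path)
  }
  is_atom <- grepl("^(ATOM|HETATM)\\b", lines)
  if (!any(is_atom))
    .fail("no ATOM/HETATM records found: empty PQR input")
  idx <- which(is_atom)
  recs <- lapply(idx, function(ln) {
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    # 10 columns without chain ID, 11 with; numeric payload is the last 5
    if (length(tok) < 10L)
      .fail("PQR parse error at line ", ln, ": expected >= 10 fields, got ",
            length(tok))
    num <- suppressWarnings(as.numeric(tok[(length(tok) - 4L):length(tok)]))
    if (any(is.na(num)))
      .fail("PQR parse error at line ", ln, ": malformed numeric field")
    list(name = tok[3], x = num[1], y = num[2], z = num[3],
         charge = num[4], radius = num[5])
  })
  out <- data.frame(
    name = vapply(recs, `[[`, "", "name"),
    x = vapply(recs, `[[`, 0, "x") / 10,  # angstrom -> nm
    y = vapply(recs, `[[`, 0, "y") / 10,
    z = vapply(recs, `[[`, 0, "z") / 10,
    charge = vapply(recs, `[[`, 0, "charge"),
    radius = vapply(recs, `[[`, 0, "radius") / 10,
    stringsAsFactors = FALSE)
  if (any(out$radius < 0)) .fail("PQR radius must be >= 0")
  out
}

#' Write atom records as a PQR file
#'
#' Inverse of [read_pqr()]: emits whitespace-separated ATOM records (one
#' residue `MOL 1`, no chain ID), converting nm back to angstrom.
#'
#' @param atoms Data frame as returned by [read_pqr()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(atoms, path) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  lines <- sprintf("ATOM %6d %-4s MOL %5d %11.4f %11.4f %11.4f %8.4f %7.4f",
                   seq_len(nrow(atoms)), atoms$name, 1L,
                   atoms$x * 10, atoms$y * 10, atoms$z * 10,
                   atoms$charge, atoms$radius * 10)
  writeLines(c("REMARK generated by rfetsense", lines, "END"), path)
  invisible(path)
}

#' Reduce an atom list to a probe state
#'
#' Collapses a per-atom charge distribution to the net charge and the
#' charge-centroid height above the substrate plane used by the interface
#' model. The centroid is |charge|-weighted; for a net-neutral distribution
#' (sum of |charge| = 0) it falls back to the geometric centroid.
#'
#' @param atoms Data frame of atom records (see [read_pqr()]).
#' @param substrate_z z-coordinate of the substrate plane, nm (default 0).
#' @param label `"unbound"` or `"bound"`.
#' @return A [probe_state()] with `net_charge` = sum of charges and
#'   `height` = weighted mean of `|z - substrate_z|`.
#' @export
probe_state_from_atoms <- function(atoms, substrate_z = 0,
                                   label = c("unbound", "bound")) {
  label <- match.arg(label)
  if (!is.data.frame(atoms) || nrow(atoms) == 0)
    .fail("empty atom list")
  w <- abs(atoms$charge)
  if (sum(w) == 0) w <- rep(1, nrow(atoms))
  h <- sum(w * abs(atoms$z - substrate_z)) / sum(w)
  probe_state(label = label, net_charge = sum(atoms$charge), height = h)
}
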