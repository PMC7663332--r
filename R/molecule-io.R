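# Structure file I/O: SDF V2000 (read via ChemmineR, written by a small
# in-package formatter) and XYZ (no connectivity; bonds inferred).
# Per-atom partial charges travel in the SDF property block under the data
# field ATOM.PARTIAL.CHARGES, one "index charge" pair per line.

.charge_field <- "ATOM.PARTIAL.CHARGES"

#' Read 3D structures from SDF or XYZ
#'
#' SDF V2000 records are parsed with ChemmineR; elements, coordinates and
#' the bond block are taken verbatim.  XYZ files (element x y z per atom,
#' optionally a 4th numeric column of partial charges) carry no bonds, so
#' connectivity is inferred from covalent radii via [inferBonds()].
#'
#' With `chargeSource = "file"` per-atom charges must be present (SDF data
#' field `ATOM.PARTIAL.CHARGES`, or the 4th XYZ column); with `"assign"`
#' they are computed by [assignCharges()] (iterative electronegativity
#' equalization).
#'
#' @param path input file.
#' @param format `"sdf"` or `"xyz"`.
#' @param chargeSource `"file"` or `"assign"`.
#' @param radiusTable van der Waals radius table (default Bondi).
#' @param bondTol covalent-radius-sum tolerance for XYZ bond inference.
#' @return list of [Molecule-class] objects.
#' @export
readStructures <- function(path, format = c("sdf", "xyz"),
                           chargeSource = c("file", "assign"),
                           radiusTable = defaultRadiusTable(),
                           bondTol = 1.2) {
  format <- match.arg(format)
  chargeSource <- match.arg(chargeSource)
  mols <- switch(format,
    sdf = .read_sdf(path, radiusTable),
    xyz = .read_xyz(path, radiusTable, bondTol)
  )
  lapply(seq_along(mols), function(i) {
    m <- mols[[i]]
    if (chargeSource == "assign") {
      m <- assignCharges(m)
    } else if (!isTRUE(attr(m, "chargesFromFile"))) {
      stop("record ", i, ": no per-atom charges in file ",
           "(expected data field ", .charge_field, " or a 4th XYZ column)")
    }
    attr(m, "chargesFromFile") <- NULL
    m
  })
}

.read_sdf <- function(path, radiusTable) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  ok <- ChemmineR::validSDF(sdfset)
  if (!all(ok))
    stop("malformed SDF record(s) at index: ",
         paste(which(!ok), collapse = ", "))
  lapply(seq_along(sdfset), function(i) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    el <- sub("_.*$", "", rownames(ab))
    xyz <- cbind(ab[, "C1"], ab[, "C2"], ab[, "C3"])
    bb <- ChemmineR::bondblock(sdf)
    bnd <- NULL; ord <- NULL
    if (nrow(bb)) {
      bnd <- cbind(as.integer(bb[, "C1"]), as.integer(bb[, "C2"]))
      ord <- as.numeric(bb[, "C3"])
    }
    q <- numeric(length(el))
    fromFile <- FALSE
    db <- ChemmineR::datablock(sdf)
    if (.charge_field %in% names(db)) {
      entries <- strsplit(db[[.charge_field]], "\\s*__\\s*|\\n")[[1]]
      entries <- entries[nzchar(trimws(entries))]
      for (e in entries) {
        kv <- strsplit(trimws(e), "\\s+")[[1]]
        if (length(kv) != 2L)
          stop("record ", i, ": malformed ", .charge_field, " entry '", e, "'")
        q[as.integer(kv[1L])] <- as.numeric(kv[2L])
      }
      fromFile <- TRUE
    }
    hdr <- ChemmineR::header(sdf)
    m <- molecule(el, xyz, charges = q, bonds = bnd, bondOrders = ord,
                  radiusTable = radiusTable,
                  name = if (length(hdr)) unname(hdr[1L]) else "sdf")
    attr(m, "chargesFromFile") <- fromFile
    m
  })
}

.read_xyz <- function(path, radiusTable, bondTol) {
  lines <- readLines(path)
  mols <- list()
  pos <- 1L
  idx <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    idx <- idx + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L)
      stop("malformed XYZ record ", idx, ": bad atom count line")
    title <- if (pos + 1L <= length(lines)) trimws(lines[pos + 1L]) else ""
    body <- lines[seq(pos + 2L, length.out = n)]
    if (length(body) != n || anyNA(body))
      stop("malformed XYZ record ", idx, ": truncated atom block")
    toks <- strsplit(trimws(body), "\\s+")
    nf <- lengths(toks)
    if (any(nf < 4L)) stop("malformed XYZ record ", idx, ": short atom line")
    el <- vapply(toks, `[`, "", 1L)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3L)))
    if (any(!is.finite(xyz)))
      stop("malformed XYZ record ", idx, ": non-numeric coordinates")
    q <- NULL
    fromFile <- FALSE
    if (all(nf >= 5L)) {
      q <- vapply(toks, function(t) as.numeric(t[5L]), numeric(1L))
      fromFile <- TRUE
    }
    m <- molecule(el, xyz, charges = q, radiusTable = radiusTable,
                  name = if (nzchar(title)) title else paste0("xyz-", idx))
    m <- inferBonds(m, tol = bondTol)
    attr(m, "chargesFromFile") <- fromFile
    mols[[idx]] <- m
    pos <- pos + 2L + n
  }
  mols
}

#' Write molecules to an SDF V2000 file
#'
#' Coordinates are printed at the standard 4-decimal SDF precision; bond
#' orders are rounded to integers.  Partial charges are stored losslessly
#' in the property block under the `ATOM.PARTIAL.CHARGES` data field.
#'
#' @param mols a [Molecule-class] or list of them.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSDF <- function(mols, path) {
  if (is(mols, "Molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in mols) {
    n <- nAtoms(m)
    b <- bonds(m)
    lines <- c(
      m@name, "  corrqsar", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b))
    )
    xyz <- coords(m)
    for (i in seq_len(n)) {
      lines <- c(lines, sprintf(
        "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        xyz[i, 1L], xyz[i, 2L], xyz[i, 3L], elements(m)[i]))
    }
    for (k in seq_len(nrow(b))) {
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                b[k, 1L], b[k, 2L],
                                as.integer(round(m@bondOrders[k]))))
    }
    lines <- c(lines, "M  END",
               sprintf("> <%s>", .charge_field),
               sprintf("%d %.10g", seq_len(n), charges(m)),
               "", "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}
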