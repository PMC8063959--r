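#' @importFrom ChemmineOB convertFormat
#' @importFrom ChemmineR read.SDFset atomblock bondblock sdfid validSDF datablock
NULL

# Internal molecule representation: heavy-atom graph only.
#   id     - identifier string
#   atoms  - character vector of element symbols (hydrogens dropped)
#   bonds  - data.frame(a1, a2, order) with 1-based atom indices
#   smiles - canonical SMILES as produced at parse time (stereo preserved);
#            NA for molecules derived by graph editing (stereo is not tracked
#            through atom deletion)
#   origin - list(source, line)
new_molecule <- function(id, atoms, bonds, smiles = NA_character_,
                         origin = list(source = NA_character_, line = NA_integer_)) {
  stopifnot(is.character(atoms), length(atoms) >= 1L)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds)) {
    stopifnot(all(bonds$a1 >= 1L & bonds$a1 <= length(atoms)),
              all(bonds$a2 >= 1L & bonds$a2 <= length(atoms)))
  } else {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  structure(list(id = as.character(id), atoms = atoms, bonds = bonds,
                 smiles = smiles, origin = origin),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d heavy atoms, %d bonds%s>\n", x$id,
              length(x$atoms), nrow(x$bonds),
              if (!is.na(x$smiles)) paste0(" ", x$smiles) else ""))
  invisible(x)
}

#' Number of heavy atoms in a molecule or fragment
#'
#' Counts non-hydrogen atoms. The internal graph stores heavy atoms only, so
#' this is the number of (selected) atoms.
#'
#' @param m a `molecule`
#' @param atoms optional integer vector of atom indices restricting the count
#'   to a fragment; `NULL` counts the whole molecule
#' @return integer count
#' @export
heavy_atom_count <- function(m, atoms = NULL) {
  stopifnot(inherits(m, "molecule"))
  if (is.null(atoms)) return(length(m$atoms))
  atoms <- as.integer(atoms)
  if (length(atoms) && (any(is.na(atoms)) || any(atoms < 1L) || any(atoms > length(m$atoms))))
    stop("invalid atom index")
  length(unique(atoms))
}

# --- OpenBabel plumbing -----------------------------------------------------

ob_convert <- function(text, from, to) {
  # convertFormat writes OpenBabel diagnostics to the C-level stderr; invalid
  # records are skipped in the output, which is how rejects are detected.
  ChemmineOB::convertFormat(from, to, source = text)
}

strip_stereo_smiles <- function(smiles) {
  # Erase tetrahedral (@) and double-bond (/ \) descriptors; constitution is
  # untouched. [C@H] -> [CH] etc. remain valid SMILES.
  gsub("[@/\\\\]", "", smiles)
}

# Batch-canonicalize SMILES strings; returns character vector aligned with
# input, NA where OpenBabel rejected the record. An invalid record aborts the
# remainder of an OpenBabel batch, so missing records are retried one by one.
canonical_smiles_batch <- function(smiles) {
  n <- length(smiles)
  if (!n) return(character())
  run <- function(idx) {
    src <- paste0(smiles[idx], " gsidx", idx, "\n", collapse = "")
    out <- ob_convert(src, "SMI", "CAN")
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    res <- rep(NA_character_, n)
    for (ln in lines[nzchar(lines)]) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) >= 2 && grepl("^gsidx[0-9]+$", parts[2]))
        res[as.integer(sub("gsidx", "", parts[2]))] <- parts[1]
    }
    res
  }
  res <- run(seq_len(n))
  missing <- which(is.na(res))
  if (length(missing) && length(missing) < n) {
    for (i in missing) res[i] <- run(i)[i]
  } else if (length(missing) == n && n > 1L) {
    for (i in missing) res[i] <- run(i)[i]
  }
  res
}

# Parse a batch of SMILES into molecule objects via an SDF intermediate.
# Returns list(mols = list of molecule or NULL per record, ok = logical).
parse_smiles_batch <- function(smiles, ids, source = NA_character_,
                               lines = rep(NA_integer_, length(smiles))) {
  n <- length(smiles)
  stopifnot(length(ids) == n)
  mols <- vector("list", n)
  if (!n) return(list(mols = mols, ok = logical()))
  cans <- canonical_smiles_batch(smiles)
  fill <- function(idx) {
    src <- paste0(smiles[idx], " gsidx", idx, "\n", collapse = "")
    parsed <- sdf_text_to_graphs(ob_convert(src, "SMI", "SDF"))
    for (p in parsed) {
      if (!grepl("^gsidx[0-9]+$", p$title)) next
      i <- as.integer(sub("gsidx", "", p$title))
      if (is.na(i) || i < 1 || i > n) next
      if (length(p$atoms) < 1L) next
      mols[[i]] <<- new_molecule(ids[i], p$atoms, p$bonds, smiles = cans[i],
                                 origin = list(source = source, line = lines[i]))
    }
  }
  fill(seq_len(n))
  # a bad record aborts the rest of an OpenBabel batch: retry the stragglers
  missing <- which(vapply(mols, is.null, logical(1)))
  if (length(missing) < n) for (i in missing) fill(i)
  else if (n > 1L) for (i in missing) fill(i)
  list(mols = mols, ok = !vapply(mols, is.null, logical(1)))
}

# Parse SDF text (possibly many records) into raw graphs:
# list of list(title, atoms, bonds). Hydrogens are dropped.
sdf_text_to_graphs <- function(sdf_text) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdf_text, tf)
  fl <- readLines(tf)
  if (!any(nzchar(fl))) return(list())
  sdfs <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(tf, skipErrors = TRUE)),
                   error = function(e) NULL)
  if (is.null(sdfs)) return(list())
  out <- vector("list", length(sdfs))
  for (k in seq_along(sdfs)) {
    sdf <- sdfs[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elems <- gsub("_.*$", "", rownames(ab))
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) {
      data.frame(a1 = integer(), a2 = integer(), order = integer())
    } else {
      data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    }
    keep <- which(elems != "H")
    if (length(keep) < length(elems)) {
      remap <- integer(length(elems)); remap[keep] <- seq_along(keep)
      bonds <- bonds[bonds$a1 %in% keep & bonds$a2 %in% keep, , drop = FALSE]
      bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
      elems <- elems[keep]
    }
    title <- ChemmineR::sdfid(sdf)
    out[[k]] <- list(title = if (length(title)) title else "", atoms = elems,
                     bonds = bonds)
  }
  out
}

# --- Reading collections ----------------------------------------------------

#' Read a molecule collection from a SMILES or SDF file
#'
#' SMILES files hold one record per line, `SMILES<whitespace>ID`, with
#' `#`-comment lines allowed. SDF files are standard V2000/V3000; the
#' identifier is taken from `id_tag` when given, falling back to the record
#' title line. Records that OpenBabel cannot parse are counted and reported in
#' the `rejects` attribute (a data.frame with line number, raw text and
#' reason), never silently dropped.
#'
#' @param path file path
#' @param format `"smiles"` or `"sdf"`
#' @param id_tag optional SDF property tag holding the identifier
#' @return a `mol_collection` (list of `molecule`) with attribute `rejects`
#' @export
read_collection <- function(path, format = c("smiles", "sdf"), id_tag = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "smiles") {
    raw <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(raw)) & !grepl("^\\s*#", raw))
    txt <- trimws(raw[keep])
    smi <- sub("\\s.*$", "", txt)
    ids <- ifelse(grepl("\\s", txt), sub("^\\S+\\s+", "", txt), "")
    ids <- ifelse(nzchar(ids), ids, paste0("mol", seq_along(txt)))
    res <- parse_smiles_batch(smi, ids, source = path, lines = keep)
    mols <- res$mols[res$ok]
    rejects <- data.frame(line = keep[!res$ok], text = txt[!res$ok],
                          reason = rep("unparsable SMILES", sum(!res$ok)),
                          stringsAsFactors = FALSE)
  } else {
    sdfs <- suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = TRUE))
    graphs <- sdf_text_to_graphs(paste(readLines(path, warn = FALSE), collapse = "\n"))
    mols <- list(); bad <- integer()
    for (k in seq_along(graphs)) {
      g <- graphs[[k]]
      if (is.null(g) || length(g$atoms) < 1L) { bad <- c(bad, k); next }
      id <- g$title
      if (!is.null(id_tag)) {
        db <- tryCatch(ChemmineR::datablock(sdfs[[k]]), error = function(e) NULL)
        if (!is.null(db) && id_tag %in% names(db)) id <- unname(db[[id_tag]])
      }
      if (!nzchar(id)) id <- paste0("mol", k)
      m <- new_molecule(id, g$atoms, g$bonds,
                        origin = list(source = path, line = k))
      m$smiles <- mol_to_smiles(m)
      mols[[length(mols) + 1L]] <- m
    }
    rejects <- data.frame(line = bad, text = rep("<sdf record>", length(bad)),
                          reason = rep("unparsable SDF record", length(bad)),
                          stringsAsFactors = FALSE)
  }
  structure(mols, class = "mol_collection", rejects = rejects)
}

#' Parse SMILES strings into molecules
#'
#' @param smiles character vector of SMILES
#' @param ids identifiers (recycled default `mol1..n`)
#' @return a `mol_collection`; unparsable entries are dropped and reported in
#'   the `rejects` attribute
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  res <- parse_smiles_batch(smiles, ids)
  structure(res$mols[res$ok], class = "mol_collection",
            rejects = data.frame(line = which(!res$ok),
                                 text = smiles[!res$ok],
                                 reason = if (any(!res$ok)) "unparsable SMILES" else character(),
                                 stringsAsFactors = FALSE))
}

#' @export
print.mol_collection <- function(x, ...) {
  rej <- attr(x, "rejects")
  cat(sprintf("<mol_collection: %d molecules%s>\n", length(x),
              if (!is.null(rej) && nrow(rej)) paste0(", ", nrow(rej), " rejects") else ""))
  invisible(x)
}

#' @export
`[.mol_collection` <- function(x, i) {
  structure(unclass(x)[i], class = "mol_collection", rejects = attr(x, "rejects"))
}

#' Write a collection to a SMILES file
#'
#' One `SMILES<space>ID` line per molecule; canonical SMILES from parse time
#' are reused where available, otherwise regenerated from the heavy-atom graph.
#'
#' @param mols a `mol_collection` or list of `molecule`
#' @param path output file
#' @return invisibly, the written lines
#' @export
write_collection <- function(mols, path) {
  smi <- vapply(mols, function(m) {
    if (!is.na(m$smiles)) m$smiles else mol_to_smiles(m)
  }, character(1))
  ids <- vapply(mols, function(m) m$id, character(1))
  lines <- paste(smi, ids)
  writeLines(lines, path)
  invisible(lines)
}

# --- Canonical keys ---------------------------------------------------------

#' Canonical line-notation keys for a molecule
#'
#' `with_stereo` is the canonical SMILES including stereo descriptors;
#' `without_stereo` erases tetrahedral and double-bond stereo before
#' re-canonicalizing, so two structures differing only in stereochemistry
#' share the same `without_stereo` key. Keys are stable under input atom-order
#' permutation.
#'
#' @param m a `molecule`
#' @return list with elements `with_stereo`, `without_stereo`
#' @export
canonical_key <- function(m) {
  stopifnot(inherits(m, "molecule"))
  base <- if (!is.na(m$smiles)) m$smiles else mol_to_smiles(m)
  ws <- canonical_smiles_batch(base)
  wos <- canonical_smiles_batch(strip_stereo_smiles(base))
  list(with_stereo = ws[1], without_stereo = wos[1])
}

# Batched keys for a whole collection; returns data.frame(id, with_stereo,
# without_stereo).
collection_keys <- function(mols) {
  smi <- vapply(mols, function(m) if (!is.na(m$smiles)) m$smiles else mol_to_smiles(m),
                character(1))
  data.frame(id = vapply(mols, function(m) m$id, character(1)),
             with_stereo = canonical_smiles_batch(smi),
             without_stereo = canonical_smiles_batch(strip_stereo_smiles(smi)),
             stringsAsFactors = FALSE)
}

# --- Graph -> SMILES --------------------------------------------------------

# Serialize molecule graphs to a V2000 SDF text (no coordinates, no stereo).
mols_to_sdf_text <- function(mols, titles = NULL) {
  blocks <- character(length(mols))
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    na <- length(m$atoms); nb <- nrow(m$bonds)
    title <- if (is.null(titles)) m$id else titles[k]
    atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          0, 0, 0, m$atoms)
    bond_lines <- if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                                  m$bonds$a1, m$bonds$a2, m$bonds$order) else character()
    blocks[k] <- paste(c(title, "  glycoscan", "",
                         sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
                         atom_lines, bond_lines, "M  END", "$$$$"),
                       collapse = "\n")
  }
  paste0(paste(blocks, collapse = "\n"), "\n")
}

# Canonical SMILES for molecules that only exist as graphs (aglycones,
# extracted moieties). Open valences are hydrogen-saturated implicitly.
mols_to_smiles <- function(mols) {
  if (!length(mols)) return(character())
  sdf <- mols_to_sdf_text(mols, titles = paste0("gsidx", seq_along(mols)))
  out <- ob_convert(sdf, "SDF", "CAN")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  res <- rep(NA_character_, length(mols))
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2 && grepl("^gsidx[0-9]+$", parts[2])) {
      i <- as.integer(sub("gsidx", "", parts[2]))
      res[i] <- parts[1]
    }
  }
  res
}

mol_to_smiles <- function(m) {
  if (!length(m$atoms)) return(NA_character_)
  mols_to_smiles(list(m))[1]
}

#' Canonical SMILES of a molecule
#'
#' @param m a `molecule`
#' @return character SMILES (stereo preserved only for molecules as parsed;
#'   graph-derived structures such as aglycones are emitted without stereo)
#' @export
as_smiles <- function(m) {
  stopifnot(inherits(m, "molecule"))
  if (!is.na(m$smiles)) m$smiles else mol_to_smiles(m)
}

# --- Subsetting -------------------------------------------------------------

# Restrict a molecule to a set of atoms (1-based indices); bonds within the
# set are kept; `orig` attribute maps new indices to indices in `m` (composed
# with any existing map so records can always be reported against the
# original input molecule).
subset_molecule <- function(m, keep, id = m$id) {
  keep <- sort(unique(as.integer(keep)))
  stopifnot(all(keep >= 1L), all(keep <= length(m$atoms)))
  remap <- integer(length(m$atoms)); remap[keep] <- seq_along(keep)
  b <- m$bonds[m$bonds$a1 %in% keep & m$bonds$a2 %in% keep, , drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  rownames(b) <- NULL
  out <- new_molecule(id, m$atoms[keep], b, smiles = NA_character_, origin = m$origin)
  prev <- attr(m, "orig_map")
  attr(out, "orig_map") <- if (is.null(prev)) keep else prev[keep]
  out
}

# Map atom indices of a (possibly repeatedly) subset molecule back to the
# original molecule's indexing.
orig_atoms <- function(m, atoms) {
  map <- attr(m, "orig_map")
  if (is.null(map)) as.integer(atoms) else map[as.integer(atoms)]
}
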