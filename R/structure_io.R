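# Structure I/O: fixed-column PDB and minimal mmCIF atom_site readers, PDB
# writer. Author residue numbering is preserved verbatim; no renumbering.

# element guess from a PDB atom name when the element column is blank.
# Two-character elements occurring in protein/nucleic models are handled;
# everything else falls back to the first alphabetic character.
guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  if (two %in% c("FE", "ZN", "MG", "MN", "CL", "NA", "BR", "CA2")) return(two)
  first <- regmatches(nm, regexpr("[A-Z]", nm))
  if (length(first) == 0L) return("X")
  first
}

#' Read an atomic model from PDB or mmCIF
#'
#' Loads all ATOM records; HETATM records are loaded with `is_hetero` set.
#' Hydrogens are retained (flagged by element); downstream area/energy code
#' removes them. Numbering is the author's.
#'
#' @param path file path
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension, falling back
#'   to content sniffing)
#' @param label provenance label; defaults to the file name
#' @return a [fibril_model()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else if (ext %in% c("pdb", "ent")) "pdb" else {
      head1 <- readLines(path, n = 50L, warn = FALSE)
      if (any(grepl("^data_|^loop_|_atom_site\\.", head1))) "mmcif" else "pdb"
    }
  }
  atoms <- switch(format, pdb = parse_pdb(path), mmcif = parse_mmcif(path))
  if (nrow(atoms) == 0L) stop("empty model: no ATOM/HETATM records in ", path)
  fibril_model(atoms, label = label)
}

parse_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  sel <- which(rec == "ATOM  " | rec == "HETATM")
  if (!length(sel)) return(empty_atom_table())
  ln <- lines[sel]
  bad <- nchar(ln) < 54
  if (any(bad)) {
    stop(sprintf("unparsable PDB record at line %d: coordinate fields truncated",
                 sel[which(bad)[1]]))
  }
  f <- function(a, b) substr(ln, a, b)
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v)) {
      stop(sprintf("unparsable PDB %s field at line %d: '%s'",
                   what, sel[which(is.na(v))[1]], s[which(is.na(v))[1]]))
    }
    v
  }
  element <- trimws(f(77, 78))
  name <- f(13, 16)
  no_elem <- element == ""
  if (any(no_elem)) {
    element[no_elem] <- vapply(name[no_elem], guess_element, character(1))
  }
  occ_str <- trimws(f(55, 60))
  occ <- ifelse(occ_str == "", 1, suppressWarnings(as.numeric(occ_str)))
  occ[is.na(occ)] <- 1
  data.frame(
    serial = as.integer(num(f(7, 11), "serial")),
    name = trimws(name),
    element = toupper(element),
    alt_loc = trimws(f(17, 17)),
    res_name = trimws(f(18, 20)),
    chain_id = trimws(f(22, 22)),
    res_seq = as.integer(num(f(23, 26), "resSeq")),
    x = num(f(31, 38), "x"),
    y = num(f(39, 46), "y"),
    z = num(f(47, 54), "z"),
    occupancy = pmin(pmax(occ, 0), 1),
    is_hetero = rec[sel] == "HETATM",
    stringsAsFactors = FALSE
  )
}

# Minimal mmCIF reader: the _atom_site loop only, whitespace-tokenised.
# Sufficient for wwPDB coordinate files; does not implement multi-line
# semicolon text fields inside atom_site (never used there).
parse_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tagged <- grep("^_atom_site\\.", lines)
  if (!length(tagged)) stop("no _atom_site loop found in mmCIF file: ", path)
  tags <- sub("^_atom_site\\.", "", trimws(lines[tagged]))
  body_start <- max(tagged) + 1L
  body_end <- body_start
  n <- length(lines)
  while (body_end <= n) {
    l <- trimws(lines[body_end])
    if (l == "" || startsWith(l, "_") || startsWith(l, "loop_") ||
        startsWith(l, "#") || startsWith(l, "data_")) break
    body_end <- body_end + 1L
  }
  body <- lines[body_start:(body_end - 1L)]
  if (!length(body)) stop("empty _atom_site loop in ", path)
  toks <- strsplit(trimws(body), "[[:space:]]+")
  nf <- lengths(toks)
  if (any(nf != length(tags))) {
    stop(sprintf("unparsable mmCIF atom_site row at line %d: %d fields, expected %d",
                 body_start + which(nf != length(tags))[1] - 1L,
                 nf[which(nf != length(tags))[1]], length(tags)))
  }
  m <- do.call(rbind, toks)
  colnames(m) <- tags
  pick <- function(...) {
    for (t in c(...)) if (t %in% tags) return(m[, t])
    NULL
  }
  grp <- pick("group_PDB")
  name <- pick("auth_atom_id", "label_atom_id")
  elem <- pick("type_symbol")
  alt <- pick("label_alt_id")
  resn <- pick("auth_comp_id", "label_comp_id")
  chain <- pick("auth_asym_id", "label_asym_id")
  seq <- pick("auth_seq_id", "label_seq_id")
  if (is.null(name) || is.null(resn) || is.null(chain) || is.null(seq)) {
    stop("mmCIF atom_site loop lacks atom/residue/chain/seq tags; found: ",
         paste(tags, collapse = ", "))
  }
  xs <- pick("Cartn_x"); ys <- pick("Cartn_y"); zs <- pick("Cartn_z")
  occ <- pick("occupancy")
  serial <- pick("id")
  strip_q <- function(v) gsub('^"|"$', "", v)
  alt <- if (is.null(alt)) "" else ifelse(alt %in% c(".", "?"), "", alt)
  elem_v <- if (is.null(elem)) vapply(strip_q(name), guess_element, character(1)) else toupper(elem)
  data.frame(
    serial = if (is.null(serial)) seq_along(xs) else as.integer(serial),
    name = strip_q(name),
    element = elem_v,
    alt_loc = alt,
    res_name = resn,
    chain_id = chain,
    res_seq = as.integer(seq),
    x = as.numeric(xs), y = as.numeric(ys), z = as.numeric(zs),
    occupancy = if (is.null(occ)) 1 else pmin(pmax(as.numeric(occ), 0), 1),
    is_hetero = if (is.null(grp)) FALSE else grp == "HETATM",
    stringsAsFactors = FALSE
  )
}

empty_atom_table <- function() {
  data.frame(serial = integer(), name = character(), element = character(),
             alt_loc = character(), res_name = character(),
             chain_id = character(), res_seq = integer(),
             x = numeric(), y = numeric(), z = numeric(),
             occupancy = numeric(), is_hetero = logical(),
             stringsAsFactors = FALSE)
}

#' Write a model to a PDB file
#'
#' Fixed-column PDB output (coordinates to 0.001 Angstrom, the format's
#' precision). Chain ids longer than one character are mapped to A, B, C...
#' with a mapping recorded in REMARK records.
#'
#' @param model a [fibril_model()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  ch <- unique(a$chain_id)
  pool <- c(LETTERS, letters, as.character(0:9))
  if (any(nchar(ch) > 1L) || length(ch) > length(pool)) {
    if (length(ch) > length(pool)) stop("too many chains for PDB chain field")
    map <- stats::setNames(pool[seq_along(ch)], ch)
  } else {
    map <- stats::setNames(ch, ch)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!identical(unname(map), names(map))) {
    for (i in seq_along(map)) {
      writeLines(sprintf("REMARK 900 CHAIN %s WRITTEN AS %s",
                         names(map)[i], map[[i]]), con)
    }
  }
  fmt_name <- function(nm, el) {
    # column alignment rule: 1-char elements start in column 14
    ifelse(nchar(nm) >= 4L | nchar(el) == 2L,
           formatC(nm, width = -4), paste0(" ", formatC(nm, width = -3)))
  }
  rec <- ifelse(a$is_hetero, "HETATM", "ATOM  ")
  lines <- sprintf("%s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec,
                   (seq_len(nrow(a)) - 1L) %% 99999L + 1L,
                   fmt_name(a$name, a$element),
                   substr(a$alt_loc, 1, 1),
                   a$res_name,
                   unname(map[a$chain_id]),
                   a$res_seq,
                   a$x, a$y, a$z,
                   a$occupancy, 0,
                   a$element)
  writeLines(lines, con)
  writeLines("END", con)
  invisible(path)
}

#' Resolve alternate conformers
#'
#' Keeps at most one atom per (chain, residue, atom name). Policies:
#' `first_conformer` keeps the alphabetically first alt-loc id (blank sorts
#' first), `highest_occupancy` keeps the highest-occupancy conformer with
#' alphabetical tie-break. Deterministic; identity when no altlocs exist.
#'
#' @param model a [fibril_model()]
#' @param policy `"first_conformer"` (default) or `"highest_occupancy"`
#' @export
resolve_altlocs <- function(model,
                            policy = c("first_conformer", "highest_occupancy")) {
  policy <- match.arg(policy)
  a <- model$atoms
  if (all(a$alt_loc == "")) return(model)
  key <- paste(a$chain_id, a$res_seq, a$name, a$is_hetero, sep = "\r")
  ord <- switch(policy,
    first_conformer = order(key, a$alt_loc),
    highest_occupancy = order(key, -a$occupancy, a$alt_loc))
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain_id, a$res_seq, a$name, a$is_hetero,
                           sep = "\r")), , drop = FALSE]
  a <- a[order(match(a$chain_id, unique(model$atoms$chain_id)), a$res_seq,
               a$serial), , drop = FALSE]
  a$alt_loc <- ""
  fibril_model(a, model$label, model$chain_info)
}

#' Select a residue segment from one chain
#'
#' Closed interval `[start_res, end_res]` on author numbering, optionally
#' restricted to named atoms (e.g. `"CA"`). Atom order is preserved.
#'
#' @param model a [fibril_model()]
#' @param chain_id chain identifier
#' @param start_res,end_res first and last author residue numbers (inclusive)
#' @param atom_filter character vector of atom names, or `"all"`
#' @export
select_segment <- function(model, chain_id, start_res, end_res,
                           atom_filter = "all") {
  if (start_res > end_res) stop("start_res must be <= end_res")
  if (!chain_id %in% model$atoms$chain_id) {
    stop("chain '", chain_id, "' not present (chains: ",
         paste(chain_ids(model), collapse = ", "), ")")
  }
  a <- model$atoms
  keep <- a$chain_id == chain_id & a$res_seq >= start_res & a$res_seq <= end_res
  if (!identical(atom_filter, "all")) keep <- keep & a$name %in% atom_filter
  if (!any(keep)) {
    stop(sprintf("empty selection: chain %s residues %d-%d (atoms: %s)",
                 chain_id, start_res, end_res,
                 paste(atom_filter, collapse = ",")))
  }
  ci <- model$chain_info
  if (!is.null(ci)) ci <- ci[ci$chain_id == chain_id, , drop = FALSE]
  fibril_model(a[keep, , drop = FALSE],
               sprintf("%s[%s:%d-%d]", model$label, chain_id, start_res, end_res),
               ci)
}
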