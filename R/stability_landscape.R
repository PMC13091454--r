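# Two-axis fibril stability landscape: dG per chain vs dG per residue,
# merging computed summaries with externally tabulated structures, and
# classification against the ex vivo stability band.

#' A point on the stability landscape
#'
#' @param label structure label
#' @param source_class one of `human_brain`, `recombinant`, `mouse_seeded`,
#'   `cell_seeded`, `this_work`
#' @param dG_chain,dG_residue stabilization energies (kcal/mol)
#' @param compensated whether RNA charge compensation was applied
#' @param n_residues optional ordered-residue count; if given, consistency
#'   of `dG_residue * n` with `dG_chain` is checked to 0.05 kcal/mol x n
#'   (table rounding)
#' @export
landscape_point <- function(label, source_class, dG_chain, dG_residue,
                            compensated = FALSE, n_residues = NA_integer_) {
  source_class <- match.arg(source_class,
                            c("human_brain", "recombinant", "mouse_seeded",
                              "cell_seeded", "this_work"))
  if (!is.na(n_residues)) {
    if (abs(dG_residue * n_residues - dG_chain) > 0.05 * n_residues + 1e-9) {
      stop(sprintf("inconsistent point '%s': %g x %d != %g kcal/mol",
                   label, dG_residue, n_residues, dG_chain))
    }
  }
  structure(list(label = label, source_class = source_class,
                 dG_chain = dG_chain, dG_residue = dG_residue,
                 compensated = compensated, n_residues = n_residues),
            class = "landscape_point")
}

#' @export
as.data.frame.landscape_point <- function(x, ...) {
  data.frame(label = x$label, source_class = x$source_class,
             dG_chain = x$dG_chain, dG_residue = x$dG_residue,
             compensated = x$compensated, n_residues = x$n_residues,
             stringsAsFactors = FALSE)
}

points_to_df <- function(points) {
  do.call(rbind, lapply(points, as.data.frame))
}

#' Ex vivo stability band
#'
#' Default endpoints -47 to -29 kcal/mol per chain, the approximate range
#' spanned by patient-derived (ex vivo) tau folds; endpoints are inclusive
#' and overridable since the range is approximate.
#'
#' @param lower,upper band limits, kcal/mol per chain (lower < upper)
#' @export
stability_band <- function(lower = -47, upper = -29) {
  if (!(lower < upper)) stop("band requires lower < upper")
  structure(list(lower = lower, upper = upper), class = "stability_band")
}

#' Classify a point against the ex vivo band
#'
#' More negative dG per chain = more stable, so `below_band` means more
#' stable than every ex vivo fold and `above_band` less stable.
#'
#' @param point a [landscape_point()] or a bare dG-per-chain value
#' @param band a [stability_band()]
#' @return `"below_band"`, `"in_band"`, or `"above_band"`
#' @export
classify_stability <- function(point, band = stability_band()) {
  dg <- if (inherits(point, "landscape_point")) point$dG_chain else as.numeric(point)
  if (dg < band$lower) "below_band"
  else if (dg <= band$upper) "in_band"
  else "above_band"
}

#' Load an Amyloid-Atlas-style table of fibril energies
#'
#' Reads a delimited table with columns mappable to label, source class,
#' dG per chain and dG per residue. Column matching is by the `mapping`
#' argument or, failing that, case-insensitive name heuristics. Rows with
#' missing energies are skipped; the skip count is reported via message and
#' `attr(, "n_skipped")`.
#'
#' @param path CSV/TSV path (delimiter sniffed from the header line)
#' @param mapping optional named list: `label`, `source_class`, `dG_chain`,
#'   `dG_residue`, optionally `n_residues`, each naming a column
#' @return list of [landscape_point()]
#' @export
load_atlas_table <- function(path, mapping = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  find_col <- function(role, patterns) {
    if (!is.null(mapping[[role]])) {
      if (!mapping[[role]] %in% names(tab)) {
        stop("mapped column '", mapping[[role]], "' for ", role,
             " not found; headers: ", paste(names(tab), collapse = ", "))
      }
      return(mapping[[role]])
    }
    hit <- which(grepl(patterns, names(tab), ignore.case = TRUE))
    if (length(hit)) names(tab)[hit[1]] else NA_character_
  }
  cols <- c(label = find_col("label", "label|structure|pdb|name"),
            source_class = find_col("source_class", "source|class|origin"),
            dG_chain = find_col("dG_chain", "chain"),
            dG_residue = find_col("dG_residue", "residue"))
  if (anyNA(cols)) {
    stop("could not map roles [", paste(names(cols)[is.na(cols)], collapse = ", "),
         "] onto table headers: ", paste(names(tab), collapse = ", "))
  }
  canon_class <- function(s) {
    s <- tolower(trimws(s))
    ifelse(grepl("human|brain|ex", s), "human_brain",
    ifelse(grepl("mouse", s), "mouse_seeded",
    ifelse(grepl("cell", s), "cell_seeded",
    ifelse(grepl("this", s), "this_work", "recombinant"))))
  }
  dgc <- suppressWarnings(as.numeric(tab[[cols["dG_chain"]]]))
  dgr <- suppressWarnings(as.numeric(tab[[cols["dG_residue"]]]))
  ok <- !is.na(dgc) & !is.na(dgr)
  n_skipped <- sum(!ok)
  if (n_skipped) message(n_skipped, " row(s) skipped for missing energies")
  pts <- lapply(which(ok), function(i) {
    landscape_point(as.character(tab[[cols["label"]]][i]),
                    canon_class(tab[[cols["source_class"]]][i]),
                    dgc[i], dgr[i])
  })
  attr(pts, "n_skipped") <- n_skipped
  pts
}

#' Export the landscape as a machine-readable plot specification
#'
#' Writes JSON holding the points (ordered deterministically by label,
#' compensated last within a label), before/after compensation links for
#' labels appearing both ways, and the two band lines.
#'
#' @param points list of [landscape_point()]
#' @param band a [stability_band()]
#' @param out output path (JSON)
#' @return `out`, invisibly
#' @export
export_landscape <- function(points, band = stability_band(), out) {
  if (!length(points)) stop("no landscape points to export")
  df <- points_to_df(points)
  df <- df[order(df$label, df$compensated), , drop = FALSE]
  df$class <- vapply(df$dG_chain, classify_stability, character(1), band = band)
  paired <- names(which(table(df$label) == 2L))
  links <- lapply(paired, function(lb) {
    sub <- df[df$label == lb, ]
    if (!setequal(sub$compensated, c(FALSE, TRUE))) return(NULL)
    list(label = lb,
         before = sub$dG_chain[!sub$compensated][1],
         after = sub$dG_chain[sub$compensated][1])
  })
  links <- links[!vapply(links, is.null, logical(1))]
  spec <- list(points = df,
               band_lines = c(band$lower, band$upper),
               links = links)
  jsonlite::write_json(spec, out, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out)
}

#' Reload a landscape exported by [export_landscape()]
#' @param path JSON path
#' @return list with `points` (list of [landscape_point()]), `band`, `links`
#' @export
load_landscape <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(spec$links)) {
    spec$links <- lapply(seq_len(nrow(spec$links)),
                         function(i) as.list(spec$links[i, ]))
  }
  pts <- lapply(seq_len(nrow(spec$points)), function(i) {
    p <- spec$points[i, ]
    landscape_point(p$label, p$source_class, p$dG_chain, p$dG_residue,
                    compensated = p$compensated,
                    n_residues = if ("n_residues" %in% names(p) &&
                                     !is.null(p$n_residues)) p$n_residues else NA_integer_)
  })
  list(points = pts,
       band = stability_band(spec$band_lines[1], spec$band_lines[2]),
       links = spec$links)
}
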