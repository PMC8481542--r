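#' Read an atomic structure from PDB format
#'
#' Parses fixed-column ATOM/HETATM records into an [XLStructure-class].
#' Records carrying an insertion code are rejected (dropped with a
#' warning); for alternate locations only altloc 'A' or blank is kept.
#' Of a multi-model (e.g. NMR) file only one MODEL is read, the first by
#' default — an explicit `model` makes a conformer choice reproducible.
#'
#' @param file path to a PDB file, or `NULL` when `text` is given.
#' @param text character scalar/vector of PDB content (alternative to `file`).
#' @param id structure identifier; defaults to the file base name.
#' @param model 1-based MODEL number to read from a multi-model file.
#' @return an [XLStructure-class].
#' @examples
#' s <- buildIdealHelix(5)
#' s2 <- parsePdb(text = writePdb(s), id = "helix")
#' @export
parsePdb <- function(file = NULL, text = NULL, id = NULL, model = 1L) {
  if (is.null(text)) {
    .stopIfNot(!is.null(file), "either 'file' or 'text' is required")
    if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(file))
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
    if (is.null(id)) id <- "structure"
  }

  # restrict to the requested MODEL block when MODEL records are present
  mstart <- grep("^MODEL", lines)
  if (length(mstart) > 0) {
    .stopIfNot(model >= 1 && model <= length(mstart),
               "model ", model, " not present (file has ",
               length(mstart), " models)")
    mend <- grep("^ENDMDL", lines)
    to <- if (model <= length(mend)) mend[model] else length(lines)
    lines <- lines[seq(mstart[model], to)]
  }

  sel <- grep("^(ATOM  |HETATM)", lines)
  if (length(sel) == 0L) stop("empty model: no ATOM/HETATM records found")

  rec <- lines[sel]
  fld <- function(a, b) substr(rec, a, b)
  altloc <- fld(17, 17)
  icode <- trimws(fld(27, 27))
  keep <- altloc %in% c(" ", "", "A") & icode == ""
  if (any(icode != ""))
    warning(sum(icode != ""), " record(s) with insertion codes rejected")

  num <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(fld(a, b)))
    bad <- which(is.na(v) & keep)
    if (length(bad) > 0)
      stop("malformed ", what, " field at line ", sel[bad[1]])
    v
  }
  x <- num(31, 38, "x coordinate")
  y <- num(39, 46, "y coordinate")
  z <- num(47, 54, "z coordinate")
  resno <- suppressWarnings(as.integer(fld(23, 26)))
  bad <- which(is.na(resno) & keep)
  if (length(bad) > 0)
    stop("malformed residue number at line ", sel[bad[1]])

  atoms <- data.frame(
    chain = fld(22, 22),
    resno = resno,
    resid = trimws(fld(18, 20)),
    elety = trimws(fld(13, 16)),
    x = x, y = y, z = z,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("empty model: all records rejected")
  XLStructure(id, atoms)
}

#' Write an atomic structure in PDB format
#'
#' Emits fixed-width ATOM records with coordinates to 3 decimals,
#' terminated by END. A round trip through [parsePdb()] preserves atom
#' count, order, names and coordinates to 3 decimals.
#'
#' @param s an [XLStructure-class].
#' @param file optional output path; when `NULL` the text is returned.
#' @return invisibly (or visibly, when `file` is `NULL`) the PDB text as
#'   a character vector of lines.
#' @export
writePdb <- function(s, file = NULL) {
  .stopIfNot(is(s, "XLStructure"), "'s' must be an XLStructure")
  a <- s@atoms
  .stopIfNot(all(nchar(a$chain) == 1L), "chain ids must be 1 character")
  # PDB columns: name left-padded for 1-3 char names starting col 14
  name <- ifelse(nchar(a$elety) >= 4L, substr(a$elety, 1, 4),
                 sprintf(" %-3s", a$elety))
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(nrow(a)) %% 100000L, name, a$resid, a$chain, a$resno,
    a$x, a$y, a$z, 1, 0)
  out <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Read a cross-link table
#'
#' Reads a delimited text table of residue-level cross-links. The header
#' must name the columns `protein_a, res_a, protein_b, res_b, linker,
#' condition, approach` (extra columns pass through). Rows whose linker
#' is absent from the linker dictionary are dropped and reported via the
#' `"rejected"` attribute and a warning.
#'
#' @param file path to the table, or `NULL` when `text` is given.
#' @param text character content (alternative to `file`).
#' @param sep field separator; `","` (default) or `"\t"`.
#' @param linkers linker dictionary used to vet linker names
#'   (default [defaultLinkers()]); `NULL` skips vetting.
#' @return data.frame of cross-links, one row per link, with attribute
#'   `"rejected"` holding any rows with unknown linkers.
#' @examples
#' tab <- "protein_a,res_a,protein_b,res_b,linker,condition,approach
#' Tim23,25,Tom5,50,DSS,with_precursor,1"
#' parseCrossLinks(text = tab)
#' @export
parseCrossLinks <- function(file = NULL, text = NULL, sep = ",",
                            linkers = defaultLinkers()) {
  df <- if (is.null(text)) {
    utils::read.table(file, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, strip.white = TRUE)
  } else {
    utils::read.table(text = paste(text, collapse = "\n"), header = TRUE,
                      sep = sep, stringsAsFactors = FALSE, strip.white = TRUE)
  }
  need <- c("protein_a", "res_a", "protein_b", "res_b", "linker",
            "condition", "approach")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("cross-link table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("res_a", "res_b")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0)
      stop("non-integer residue in column ", col, " at row ", bad[1])
    df[[col]] <- v
  }
  ok <- df$condition %in% c("with_precursor", "without_precursor", "both")
  if (!all(ok))
    stop("unknown condition tag(s): ",
         paste(unique(df$condition[!ok]), collapse = ", "))
  rejected <- df[0, , drop = FALSE]
  if (!is.null(linkers) && nrow(df) > 0) {
    known <- df$linker %in% linkers$name
    if (!all(known)) {
      rejected <- df[!known, , drop = FALSE]
      warning(nrow(rejected), " link(s) with unknown linker dropped: ",
              paste(unique(rejected$linker), collapse = ", "))
      df <- df[known, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  attr(df, "rejected") <- rejected
  df
}

#' Export a cross-link network in xiNET CSV dialect
#'
#' Writes one row per link with the columns `Protein1, PepPos1, Protein2,
#' PepPos2, Score` understood by the xiNET cross-link viewer; when
#' restraint evaluations are supplied a `Satisfied` flag column is
#' appended and the flat-harmonic penalty is used as the score.
#'
#' @param links cross-link data.frame (see [parseCrossLinks()]).
#' @param evals optional result of [evaluateSet()] on the same links.
#' @param file optional output path.
#' @return the exported data.frame (invisibly when `file` given).
#' @export
exportXiNet <- function(links, evals = NULL, file = NULL) {
  out <- data.frame(
    Protein1 = links$protein_a, PepPos1 = links$res_a,
    Protein2 = links$protein_b, PepPos2 = links$res_b,
    Score = rep(1, nrow(links)),
    stringsAsFactors = FALSE)
  if (!is.null(evals)) {
    tab <- evals$table
    key <- paste(links$protein_a, links$res_a, links$protein_b, links$res_b,
                 links$linker)
    ekey <- paste(tab$protein_a, tab$res_a, tab$protein_b, tab$res_b,
                  tab$linker)
    i <- match(key, ekey)
    out$Score <- ifelse(is.na(i), NA_real_, tab$penalty[i])
    out$Satisfied <- ifelse(is.na(i), NA, tab$satisfied[i])
  }
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
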