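# GenBank flat-file and InterProScan TSV input, report-table output.
#
# Internal coordinates are 0-based half-open throughout the package;
# GenBank's 1-based inclusive convention is converted at this boundary
# and nowhere else.

#' Construct a CDS feature
#'
#' @param protein_id protein identifier.
#' @param start,end 0-based half-open coordinates on the genome.
#' @param strand `"+"` or `"-"`.
#' @param product free-text product description (may be empty).
#' @param translation amino-acid string (may be empty; then `flagged` should
#'   be `TRUE`).
#' @param segments integer matrix with columns `start`, `end` (0-based
#'   half-open) for joined multi-interval features; defaults to the single
#'   interval `[start, end)`.
#' @param flagged `TRUE` when no translation could be obtained.
#' @return an object of class `cds_feature`.
#' @export
cds_feature <- function(protein_id, start, end, strand, product = "",
                        translation = "", segments = NULL, flagged = FALSE) {
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-', got '%s'", strand)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stopf("invalid CDS coordinates [%s, %s)", start, end)
  if (is.null(segments)) segments <- cbind(start = start, end = end)
  structure(list(protein_id = as.character(protein_id), start = start,
                 end = end, strand = strand, product = as.character(product),
                 translation = as.character(translation),
                 segments = segments, flagged = isTRUE(flagged)),
            class = "cds_feature")
}

#' Construct a genome record
#'
#' @param accession accession (versioned where available).
#' @param name locus / phage name.
#' @param length_bp genome length in bp.
#' @param sequence nucleotide string, or `NULL` for feature-table-only
#'   records.
#' @param cds list of [cds_feature()] objects; re-sorted by start coordinate
#'   (stable for ties).
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(accession, name = accession, length_bp,
                          sequence = NULL, cds = list()) {
  length_bp <- as.integer(length_bp)
  if (is.na(length_bp) || length_bp <= 0L) stopf("length_bp must be positive")
  if (!is.null(sequence)) {
    if (nchar(sequence) != length_bp)
      stopf("record %s: sequence length %d disagrees with declared length %d",
            accession, nchar(sequence), length_bp)
  }
  bad <- vapply(cds, function(f) f$end > length_bp, logical(1))
  if (any(bad))
    stopf("record %s: CDS extends beyond genome length", accession)
  if (length(cds)) {
    ord <- order(vapply(cds, `[[`, integer(1), "start"))  # stable
    cds <- cds[ord]
  }
  structure(list(accession = as.character(accession), name = as.character(name),
                 length_bp = length_bp, sequence = sequence, cds = cds),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s), %d bp, %d CDS, sequence: %s\n",
              x$accession, x$name, x$length_bp, length(x$cds),
              if (is.null(x$sequence)) "absent" else "present"))
  invisible(x)
}

# ---- GenBank reading ---------------------------------------------------

# Parse a GenBank location string ("123..456", "complement(join(..))",
# "<1..>99") into list(strand, segments matrix 0-based half-open).
# Join intervals keep feature order. Returns NULL on failure.
parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  segs <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^\\d+$", p)) {
      ab <- rep(as.integer(p), 2L)
    } else return(NULL)
    c(ab[1] - 1L, ab[2])
  })
  if (any(vapply(segs, is.null, logical(1)))) return(NULL)
  m <- do.call(rbind, segs)
  colnames(m) <- c("start", "end")
  list(strand = strand, segments = m)
}

# split raw feature-table lines into per-feature chunks
split_features <- function(lines) {
  is_key <- grepl("^ {5}\\S", lines)
  idx <- which(is_key)
  lapply(seq_along(idx), function(i) {
    to <- if (i < length(idx)) idx[i + 1] - 1L else length(lines)
    lines[idx[i]:to]
  })
}

parse_qualifiers <- function(lines) {
  txt <- paste(trimws(lines), collapse = "\n")
  # qualifier starts at a line beginning with '/'
  pieces <- strsplit(txt, "\n(?=/)", perl = TRUE)[[1]]
  quals <- list()
  for (p in pieces[-1]) {
    p <- sub("^/", "", p)
    if (grepl("=", p)) {
      key <- sub("=.*$", "", p)
      val <- sub("^[^=]*=", "", p)
      val <- gsub("^\"|\"$", "", val)
      if (key == "translation") val <- gsub("\\s", "", val) else
        val <- gsub("\n", " ", val)
    } else { key <- p; val <- TRUE }
    quals[[key]] <- val
  }
  quals
}

extract_cds_translation <- function(sequence, segments, strand) {
  nt <- paste(vapply(seq_len(nrow(segments)), function(i)
    substr(sequence, segments[i, 1] + 1L, segments[i, 2]), character(1)),
    collapse = "")
  dna <- Biostrings::DNAString(gsub("[^ACGTNacgtn]", "N", nt))
  if (strand == "-") dna <- Biostrings::reverseComplement(dna)
  if (length(dna) %% 3 != 0) return(NULL)
  aa <- as.character(Biostrings::translate(
    dna, genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Read genome records from a GenBank flat file
#'
#' Parses one or more records (LOCUS..//) with their CDS features. GenBank
#' 1-based inclusive coordinates are converted to the package's 0-based
#' half-open convention; `complement(...)` features get strand `"-"`;
#' `join(...)` features keep their interval list in feature order. CDS
#' without a `/translation` qualifier are translated from the nucleotide
#' sequence (genetic code table 11) when a sequence is present, otherwise
#' kept with an empty translation and `flagged = TRUE`.
#'
#' @param path path to a GenBank flat file.
#' @return list of [genome_record()] objects in file order.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  locus_idx <- grep("^LOCUS", lines)
  if (!length(locus_idx))
    stopf("%s: not a GenBank flat file (no LOCUS line; first line: '%s')",
          path, if (length(lines)) lines[1] else "")
  ends <- grep("^//", lines)
  records <- vector("list", length(locus_idx))
  for (r in seq_along(locus_idx)) {
    from <- locus_idx[r]
    to <- ends[ends > from][1]
    if (is.na(to)) to <- length(lines)
    rec <- lines[from:to]
    locus <- strsplit(trimws(rec[1]), "\\s+")[[1]]
    if (length(locus) < 3 || !grepl("^\\d+$", locus[3]))
      stopf("%s line %d: unparseable LOCUS line", path, from)
    name <- locus[2]; length_bp <- as.integer(locus[3])
    acc <- name
    ver <- grep("^VERSION", rec, value = TRUE)
    accl <- grep("^ACCESSION", rec, value = TRUE)
    if (length(accl)) acc <- strsplit(trimws(accl[1]), "\\s+")[[1]][2]
    if (length(ver)) {
      v <- strsplit(trimws(ver[1]), "\\s+")[[1]]
      if (length(v) >= 2) acc <- v[2]
    }
    if (is.na(acc)) acc <- name
    # sequence
    ori <- grep("^ORIGIN", rec)
    sequence <- NULL
    if (length(ori)) {
      seq_lines <- rec[(ori[1] + 1):length(rec)]
      seq_lines <- seq_lines[!grepl("^//", seq_lines)]
      sequence <- tolower(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
      if (!nzchar(sequence)) sequence <- NULL
      if (!is.null(sequence) && nchar(sequence) != length_bp)
        stopf("record %s: LOCUS length %d disagrees with sequence length %d",
              acc, length_bp, nchar(sequence))
    }
    # features
    fst <- grep("^FEATURES", rec)
    cds <- list()
    if (length(fst)) {
      fend <- if (length(ori)) ori[1] - 1L else length(rec)
      flines <- rec[(fst[1] + 1):fend]
      flines <- flines[grepl("^ ", flines)]
      for (chunk in split_features(flines)) {
        key <- sub("^\\s+(\\S+).*$", "\\1", chunk[1])
        if (key != "CDS") next
        # location may continue on lines that are not qualifiers
        qual_start <- grep("^\\s+/", chunk)[1]
        loc_lines <- if (is.na(qual_start)) chunk else chunk[seq_len(qual_start - 1L)]
        loc <- gsub("\\s", "",
                    sub("^CDS\\s*", "", paste(trimws(loc_lines), collapse = "")))
        ploc <- parse_gb_location(loc)
        if (is.null(ploc))
          stopf("%s: unparseable CDS location '%s' in record %s", path, loc, acc)
        quals <- if (is.na(qual_start)) list() else
          parse_qualifiers(chunk[qual_start:length(chunk)])
        translation <- if (!is.null(quals$translation)) quals$translation else ""
        flagged <- FALSE
        if (!nzchar(translation)) {
          tr <- if (!is.null(sequence))
            extract_cds_translation(sequence, ploc$segments, ploc$strand) else NULL
          if (is.null(tr)) flagged <- TRUE else translation <- tr
        }
        pid <- if (!is.null(quals$protein_id)) quals$protein_id else
          if (!is.null(quals$locus_tag)) quals$locus_tag else
            sprintf("%s_cds%03d", acc, length(cds) + 1L)
        cds[[length(cds) + 1L]] <- cds_feature(
          protein_id = pid,
          start = min(ploc$segments[, "start"]),
          end = max(ploc$segments[, "end"]),
          strand = ploc$strand,
          product = if (!is.null(quals$product)) quals$product else "",
          translation = sanitize_aa(translation),
          segments = ploc$segments, flagged = flagged)
      }
    }
    records[[r]] <- genome_record(accession = acc, name = name,
                                  length_bp = length_bp, sequence = sequence,
                                  cds = cds)
  }
  records
}

# ---- GenBank writing (minimal, for fixtures and the simulator) ---------

wrap_qual <- function(key, val, width = 58) {
  txt <- sprintf("/%s=\"%s\"", key, val)
  out <- character(0)
  while (nchar(txt) > width) {
    out <- c(out, substr(txt, 1, width))
    txt <- substr(txt, width + 1L, nchar(txt))
  }
  c(out, txt)
}

#' Write genome records as a minimal GenBank flat file
#'
#' Writes LOCUS, VERSION, FEATURES (source + CDS with product, protein_id
#' and translation qualifiers) and ORIGIN blocks — enough structure to
#' round-trip through [read_genbank()]. Not a full GenBank emitter.
#'
#' @param records list of [genome_record()] objects.
#' @param path output path.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (g in records) {
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   PHG",
                       g$name, g$length_bp), con)
    writeLines(sprintf("DEFINITION  %s, complete genome.", g$name), con)
    writeLines(sprintf("ACCESSION   %s", sub("\\.\\d+$", "", g$accession)), con)
    writeLines(sprintf("VERSION     %s", g$accession), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", g$length_bp), con)
    for (f in g$cds) {
      segs <- f$segments
      locs <- sprintf("%d..%d", segs[, "start"] + 1L, segs[, "end"])
      loc <- if (length(locs) > 1) sprintf("join(%s)", paste(locs, collapse = ",")) else locs
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      pad <- "                     "
      writeLines(paste0(pad, wrap_qual("product", f$product)), con)
      writeLines(paste0(pad, wrap_qual("protein_id", f$protein_id)), con)
      if (nzchar(f$translation))
        writeLines(paste0(pad, wrap_qual("translation", f$translation)), con)
    }
    if (!is.null(g$sequence)) {
      writeLines("ORIGIN", con)
      s <- g$sequence
      starts <- seq(1L, nchar(s), by = 60L)
      for (st in starts) {
        chunk <- substr(s, st, min(st + 59L, nchar(s)))
        tens <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
        writeLines(sprintf("%9d %s", st, paste(tens, collapse = " ")), con)
      }
    }
    writeLines("//", con)
  }
  invisible(NULL)
}

# ---- InterProScan-style domain scans -----------------------------------

#' Read a protein domain scan in InterProScan TSV dialect
#'
#' Accepts either the full InterProScan 5 TSV layout (protein id, MD5,
#' length, analysis, signature accession, description, start, stop, ...)
#' or the reduced six-column dialect (protein id, analysis, signature
#' accession, description, start, stop). Rows whose analysis (signature
#' database) is not in `accepted_dbs` are dropped and counted in the
#' `skip_log` attribute of the result.
#'
#' @param path path to a tab-separated file without header.
#' @param accepted_dbs character vector of accepted signature databases.
#' @return data.frame with columns `protein_id`, `signature_db`,
#'   `signature_accession`, `signature_name`, `start_aa`, `end_aa`,
#'   `score`; attribute `skip_log` is a named integer count of skipped
#'   rows per database.
#' @export
read_domain_scan <- function(path, accepted_dbs = "Pfam") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(protein_id = character(0), signature_db = character(0),
                      signature_accession = character(0),
                      signature_name = character(0),
                      start_aa = integer(0), end_aa = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (!length(lines)) {
    attr(empty, "skip_log") <- integer(0)
    return(empty)
  }
  rows <- strsplit(lines, "\t", fixed = TRUE)
  parse_row <- function(fields, i) {
    n <- length(fields)
    if (n >= 8 && grepl("^\\d+$", fields[7]) && grepl("^\\d+$", fields[8])) {
      # full InterProScan 5 layout
      out <- list(protein_id = fields[1], signature_db = fields[4],
                  signature_accession = fields[5], signature_name = fields[6],
                  start = fields[7], stop = fields[8],
                  score = if (n >= 9) fields[9] else NA)
    } else if (n >= 6) {
      out <- list(protein_id = fields[1], signature_db = fields[2],
                  signature_accession = fields[3], signature_name = fields[4],
                  start = fields[5], stop = fields[6],
                  score = if (n >= 7) fields[7] else NA)
    } else stopf("domain scan row %d: expected >= 6 tab-separated columns, got %d", i, n)
    if (!grepl("^\\d+$", out$start) || !grepl("^\\d+$", out$stop))
      stopf("domain scan row %d: non-integer start/stop ('%s', '%s')",
            i, out$start, out$stop)
    out$start <- as.integer(out$start); out$stop <- as.integer(out$stop)
    if (out$start > out$stop)
      stopf("domain scan row %d: start %d > stop %d", i, out$start, out$stop)
    if (out$start < 1L)
      stopf("domain scan row %d: start must be >= 1", i)
    out
  }
  parsed <- lapply(seq_along(rows), function(i) parse_row(rows[[i]], i))
  db <- vapply(parsed, `[[`, character(1), "signature_db")
  keep <- db %in% accepted_dbs
  skip_log <- table(db[!keep])
  parsed <- parsed[keep]
  out <- if (length(parsed)) data.frame(
    protein_id = vapply(parsed, `[[`, character(1), "protein_id"),
    signature_db = vapply(parsed, `[[`, character(1), "signature_db"),
    signature_accession = vapply(parsed, `[[`, character(1), "signature_accession"),
    signature_name = vapply(parsed, `[[`, character(1), "signature_name"),
    start_aa = vapply(parsed, `[[`, integer(1), "start"),
    end_aa = vapply(parsed, `[[`, integer(1), "stop"),
    score = vapply(parsed, function(p) suppressWarnings(as.numeric(p$score)), numeric(1)),
    stringsAsFactors = FALSE) else empty
  attr(out, "skip_log") <- c(unclass(skip_log))
  out
}

#' Cross-link domain hits against a genome set
#'
#' Verifies that every hit's `protein_id` occurs among the CDS of the
#' given genomes. Orphan hits are reported with a warning and returned in
#' the `orphans` attribute; they are never silently dropped from the
#' returned table.
#'
#' @param hits data.frame from [read_domain_scan()].
#' @param genomes list of [genome_record()] objects.
#' @return `hits`, with attribute `orphans` (character vector of unknown
#'   protein ids).
#' @export
cross_link_hits <- function(hits, genomes) {
  known <- unlist(lapply(genomes, function(g)
    vapply(g$cds, `[[`, character(1), "protein_id")))
  orphans <- setdiff(unique(hits$protein_id), known)
  if (length(orphans))
    warning(sprintf("%d domain hit protein id(s) not found in genome set: %s",
                    length(orphans), paste(orphans, collapse = ", ")),
            call. = FALSE)
  attr(hits, "orphans") <- orphans
  hits
}

# ---- report tables -----------------------------------------------------

#' Write a report table as TSV
#'
#' Writes a header line plus tab-separated rows. Rows are stably sorted by
#' the given key columns; numeric columns whose name contains "percent" or
#' ends in "pct" are printed with exactly two decimals.
#'
#' @param rows data.frame of uniform records.
#' @param path output path.
#' @param key character vector of column names used for the stable sort
#'   (default: no re-ordering).
#' @export
write_table <- function(rows, path, key = NULL) {
  stopifnot(is.data.frame(rows))
  if (!is.null(key) && nrow(rows)) {
    missing_key <- setdiff(key, names(rows))
    if (length(missing_key)) stopf("unknown key column(s): %s",
                                   paste(missing_key, collapse = ", "))
    rows <- rows[do.call(order, rows[key]), , drop = FALSE]
  }
  out <- rows
  pct_cols <- grepl("percent|pct$", names(out), ignore.case = TRUE)
  for (j in which(pct_cols & vapply(out, is.numeric, logical(1))))
    out[[j]] <- sprintf("%.2f", out[[j]])
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    TRUE
  }, error = function(e) stopf("cannot write table to '%s': %s", path,
                               conditionMessage(e)))
  invisible(NULL)
}
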