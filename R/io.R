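#' Read an annotated genome from standard formats
#'
#' Reads either a FASTA + GFF3 pair or a GenBank flat file into an
#' [annotated_genome()]. External coordinates are 1-based inclusive (the
#' GenBank/GFF3 convention) and are converted to the package's internal
#' 0-based half-open intervals.
#'
#' @param path For `"fasta+gff3"`, a path prefix: `<path>.fasta` and
#'   `<path>.gff3` are read (explicit `.fasta`/`.fna`/`.gff3`/`.gff`
#'   extensions on `path` are also accepted for the sequence file, with the
#'   annotation looked up next to it). For `"genbank"`, the flat file path.
#' @param format `"fasta+gff3"` or `"genbank"`.
#' @return An [annotated_genome()].
#' @seealso [write_genome()]
#' @export
read_genome <- function(path, format = c("fasta+gff3", "genbank")) {
  format <- match.arg(format)
  if (format == "genbank") return(read_genbank(path))
  pr <- io_prefix(path)
  fa <- first_existing(paste0(pr, c(".fasta", ".fna", ".fa")))
  gff <- first_existing(paste0(pr, c(".gff3", ".gff")))
  if (is.na(fa)) abort(sprintf("no FASTA found for prefix '%s'", pr))
  if (is.na(gff)) abort(sprintf("no GFF3 found for prefix '%s'", pr))
  seqs <- Biostrings::readDNAStringSet(fa)
  if (length(seqs) != 1L) abort("expected exactly one FASTA record")
  id <- sub("\\s.*$", "", names(seqs)[1])
  seq <- toupper(as.character(seqs[[1]]))
  gr <- rtracklayer::import(gff, format = "gff3")
  md <- S4Vectors::mcols(gr)
  circular <- TRUE
  keep <- rep(TRUE, length(gr))
  type <- as.character(md$type)
  if ("type" %in% names(md) && any(type == "region")) {
    i <- which(type == "region")[1]
    if (!is.null(md$Is_circular)) {
      circ_attr <- as.character(md$Is_circular[i])
      circular <- isTRUE(tolower(circ_attr) == "true")
    }
    keep[type == "region"] <- FALSE
  }
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  kind <- if (!is.null(md$kind) && !all(is.na(md$kind))) {
    ifelse(is.na(md$kind), gff_type_to_kind(type), as.character(md$kind))
  } else {
    gff_type_to_kind(type)
  }
  lt <- if (!is.null(md$locus_tag)) as.character(md$locus_tag)
        else if (!is.null(md$ID)) as.character(md$ID)
        else sprintf("feat%05d", seq_along(gr))
  f <- feature_table(
    kind = kind,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    locus_tag = lt,
    product = if (!is.null(md$product)) as.character(md$product)
              else NA_character_,
    family = if (!is.null(md$family)) as.character(md$family)
             else NA_character_)
  f$wraps_origin <- f$end > nchar(seq)
  annotated_genome(id, seq, f, circular = circular)
}

#' Write an annotated genome
#'
#' Inverse of [read_genome()]: emits FASTA + GFF3 (1-based inclusive
#' coordinates, GFF3 escaping handled by \pkg{rtracklayer}) or a GenBank
#' flat file. Round trip through either format preserves sequence,
#' features, strands and coordinates exactly.
#'
#' @param genome An [annotated_genome()].
#' @param path Path prefix (fasta+gff3) or file path (genbank).
#' @param format `"fasta+gff3"` or `"genbank"`.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, format = c("fasta+gff3", "genbank")) {
  format <- match.arg(format)
  if (format == "genbank") return(write_genbank(genome, path))
  pr <- io_prefix(path)
  seqs <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$id))
  Biostrings::writeXStringSet(seqs, paste0(pr, ".fasta"), width = 70L)
  f <- genome$features
  L <- genome_length(genome)
  reg <- GenomicRanges::GRanges(genome$id, IRanges::IRanges(1L, L),
                                strand = "+")
  S4Vectors::mcols(reg) <- S4Vectors::DataFrame(
    type = "region", kind = NA_character_, locus_tag = NA_character_,
    product = NA_character_, family = NA_character_,
    Is_circular = if (genome$circular) "true" else "false",
    phase = NA_integer_)
  if (nrow(f)) {
    gr <- GenomicRanges::GRanges(genome$id,
                                 IRanges::IRanges(f$start + 1L, f$end),
                                 strand = f$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      type = kind_to_gff_type(f$kind), kind = f$kind,
      locus_tag = f$locus_tag, product = f$product, family = f$family,
      Is_circular = NA_character_,
      phase = ifelse(f$kind %in% c("CDS", "pseudogene"), 0L, NA_integer_))
    gr <- c(reg, gr)
  } else gr <- reg
  rtracklayer::export(gr, paste0(pr, ".gff3"), format = "gff3")
  invisible(path)
}

io_prefix <- function(path) {
  sub("\\.(fasta|fna|fa|gff3|gff)$", "", path)
}

first_existing <- function(paths) {
  hit <- paths[file.exists(paths)]
  if (length(hit)) hit[1] else NA_character_
}

gff_type_to_kind <- function(type) {
  dplyr::case_when(
    type == "CDS" ~ "CDS",
    type == "pseudogene" ~ "pseudogene",
    type == "rRNA_16S" ~ "rRNA_16S",
    type == "rRNA_23S" ~ "rRNA_23S",
    type == "rRNA_5S" ~ "rRNA_5S",
    type == "tRNA" ~ "tRNA",
    type == "mobile_genetic_element" ~ "IS_element",
    type == "prophage" ~ "phage",
    TRUE ~ "other")
}

kind_to_gff_type <- function(kind) {
  dplyr::case_when(
    kind == "IS_element" ~ "mobile_genetic_element",
    kind == "phage" ~ "prophage",
    kind %in% c("rRNA_16S", "rRNA_23S", "rRNA_5S") ~ kind,
    kind == "other" ~ "misc_feature",
    TRUE ~ kind)
}

# ---- GenBank flat file (minimal subset) -------------------------------------
# No installed R package reads or writes GenBank flat files, so a compact
# parser/writer for the subset this package emits (single record; simple or
# complement() locations, join() across the origin; locus_tag / product /
# mobile_element_type / pseudo qualifiers) lives here.

read_genbank <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  loc_i <- grep("^LOCUS", lines)
  if (!length(loc_i)) abort(sprintf("%s: no LOCUS line (not GenBank?)", path))
  loc <- strsplit(trimws(lines[loc_i[1]]), "\\s+")[[1]]
  id <- loc[2]
  circular <- any(tolower(loc) == "circular")
  ori_i <- grep("^ORIGIN", lines)
  if (!length(ori_i)) abort(sprintf("%s: no ORIGIN section", path))
  seq_lines <- lines[(ori_i[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feat_i <- grep("^FEATURES", lines)
  feats <- feature_table()
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1L):(ori_i[1] - 1L)]
    starts <- grep("^ {5}\\S", block)
    if (length(starts)) {
      bounds <- c(starts, length(block) + 1L)
      rows <- vector("list", length(starts))
      for (j in seq_along(starts)) {
        chunk <- block[starts[j]:(bounds[j + 1L] - 1L)]
        rows[[j]] <- parse_gb_feature(chunk, nchar(seq), path,
                                      starts[j] + feat_i[1])
      }
      rows <- rows[!vapply(rows, is.null, logical(1))]
      if (length(rows)) feats <- bind_rows(rows)
    }
  }
  if (nrow(feats) && anyDuplicated(feats$locus_tag)) {
    feats$locus_tag <- make.unique(feats$locus_tag, sep = "_")
  }
  annotated_genome(id, seq, feats, circular = circular)
}

parse_gb_feature <- function(chunk, L, path, line_no) {
  head_line <- chunk[1]
  key <- sub("^ {5}(\\S+).*", "\\1", head_line)
  if (key == "source") return(NULL)
  loc <- sub("^ {5}\\S+\\s+", "", head_line)
  qual_lines <- if (length(chunk) > 1L) trimws(chunk[-1]) else character()
  # continuation lines of the location (no leading /)
  while (length(qual_lines) && !startsWith(qual_lines[1], "/")) {
    loc <- paste0(loc, qual_lines[1]); qual_lines <- qual_lines[-1]
  }
  quals <- parse_gb_quals(qual_lines)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wraps <- FALSE
  if (grepl("^join\\(", loc)) {
    parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
    iv <- lapply(parts, parse_gb_interval, path = path, line_no = line_no)
    a <- iv[[1]]; b <- iv[[length(iv)]]
    if (length(iv) == 2L && a[2] == L && b[1] == 1L) {
      start <- a[1] - 1L; end <- L + b[2]; wraps <- TRUE
    } else {
      start <- a[1] - 1L; end <- b[2]
    }
  } else {
    iv <- parse_gb_interval(loc, path, line_no)
    start <- iv[1] - 1L; end <- iv[2]
  }
  kind <- gb_key_to_kind(key, quals)
  feature_table(kind = kind, start = start, end = end, strand = strand,
                locus_tag = quals[["locus_tag"]] %||%
                  sprintf("gb_l%06d", line_no),
                product = quals[["product"]] %||% NA_character_,
                family = gb_family(quals), wraps_origin = wraps)
}

parse_gb_interval <- function(txt, path, line_no) {
  txt <- gsub("[<>]", "", trimws(txt))
  m <- regmatches(txt, regexec("^(\\d+)\\.\\.(\\d+)$", txt))[[1]]
  if (length(m) != 3L) {
    abort(sprintf("%s line %d: cannot parse location '%s'",
                  path, line_no, txt))
  }
  as.integer(m[2:3])
}

parse_gb_quals <- function(lines) {
  if (!length(lines)) return(list())
  # re-join continuation lines
  idx <- cumsum(startsWith(lines, "/"))
  joined <- vapply(split(lines, idx), paste, character(1), collapse = " ")
  out <- list()
  for (q in joined) {
    if (grepl("=", q)) {
      k <- sub("^/([^=]+)=.*$", "\\1", q)
      v <- sub("^/[^=]+=", "", q)
      v <- gsub('^"|"$', "", v)
      out[[k]] <- v
    } else {
      out[[sub("^/", "", q)]] <- TRUE
    }
  }
  out
}

gb_key_to_kind <- function(key, quals) {
  if (key == "CDS") {
    if (isTRUE(quals[["pseudo"]])) "pseudogene" else "CDS"
  } else if (key == "rRNA") {
    p <- tolower(quals[["product"]] %||% "")
    if (grepl("16s", p)) "rRNA_16S"
    else if (grepl("23s", p)) "rRNA_23S"
    else if (grepl("5s", p)) "rRNA_5S" else "other"
  } else if (key == "tRNA") "tRNA"
  else if (key == "mobile_element") "IS_element"
  else if (key == "misc_feature" &&
           grepl("prophage", tolower(quals[["note"]] %||% ""))) "phage"
  else "other"
}

gb_family <- function(quals) {
  met <- quals[["mobile_element_type"]]
  if (is.null(met)) return(NA_character_)
  sub("^insertion sequence:?", "", met)
}

write_genbank <- function(genome, path) {
  L <- genome_length(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "LOCUS       %-16s %s bp    DNA     %s BCT %s",
    genome$id, L, if (genome$circular) "circular" else "linear",
    format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s.", genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  f <- genome$features
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      writeLines(gb_feature_lines(f[i, ], L), con)
    }
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(genome$sequence, p, min(p + 59L, L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))),
               con)
  }
  writeLines("//", con)
  invisible(path)
}

gb_feature_lines <- function(row, L) {
  if (row$end > L) {
    loc <- sprintf("join(%d..%d,1..%d)", row$start + 1L, L, row$end - L)
  } else {
    loc <- sprintf("%d..%d", row$start + 1L, row$end)
  }
  if (row$strand == "-") loc <- sprintf("complement(%s)", loc)
  key <- switch(row$kind,
                CDS = "CDS", pseudogene = "CDS",
                rRNA_16S = "rRNA", rRNA_23S = "rRNA", rRNA_5S = "rRNA",
                tRNA = "tRNA", IS_element = "mobile_element",
                phage = "misc_feature", other = "misc_feature")
  out <- sprintf("     %-15s %s", key, loc)
  qual <- function(k, v) sprintf('                     /%s="%s"', k, v)
  out <- c(out, qual("locus_tag", row$locus_tag))
  if (row$kind == "pseudogene") {
    out <- c(out, "                     /pseudo")
  }
  prod <- row$product
  if (row$kind %in% c("rRNA_16S", "rRNA_23S", "rRNA_5S") && is.na(prod)) {
    prod <- paste(sub("rRNA_", "", row$kind), "ribosomal RNA")
  }
  if (!is.na(prod)) out <- c(out, qual("product", prod))
  if (row$kind == "IS_element") {
    fam <- if (is.na(row$family)) "" else row$family
    out <- c(out, qual("mobile_element_type",
                       paste0("insertion sequence:", fam)))
  }
  if (row$kind == "phage") {
    out <- c(out, qual("note", "prophage region"))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
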