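#' Read a SEG-like segmentation file
#'
#' SEG on disk follows the IGV dialect: tab-separated with a header, columns
#' sample, chromosome, start, end, optionally a marker count, and the mean
#' log2 copy ratio in the last column.  On-disk coordinates are 1-based
#' inclusive; in memory all intervals are 0-based half-open, so `start` is
#' decremented on read and incremented on write.
#'
#' @param path SEG file path.
#' @return data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `seg_mean` (0-based half-open).
#' @seealso [write_seg()]
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) stop("SEG file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 5) stop("SEG file needs >= 5 columns: ", path)
  seg_col <- ncol(df)
  out <- data.frame(sample = as.character(df[[1]]),
                    chrom = normalize_chrom(df[[2]]),
                    start = as.numeric(df[[3]]) - 1,
                    end = as.numeric(df[[4]]),
                    seg_mean = suppressWarnings(as.numeric(df[[seg_col]])),
                    stringsAsFactors = FALSE)
  bad <- which(!is.finite(out$seg_mean))
  if (length(bad)) stop("non-numeric seg_mean at data line ", bad[1], " of ", path)
  bad <- which(is.na(out$start) | is.na(out$end) | out$start < 0 |
                 out$start >= out$end)
  if (length(bad)) stop("malformed segment at data line ", bad[1], " of ", path)
  out
}

#' Write segments as a SEG file (IGV dialect)
#'
#' @param segments data frame as returned by [read_seg()].
#' @param path output path.
#' @export
write_seg <- function(segments, path) {
  df <- data.frame(Sample = segments$sample,
                   Chromosome = segments$chrom,
                   Start = format(segments$start + 1, scientific = FALSE, trim = TRUE),
                   End = format(segments$end, scientific = FALSE, trim = TRUE),
                   Seg.Mean = segments$seg_mean)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Orientation class of a breakend strand pair
#'
#' SV junctions are grouped by the strand pair at the two breakends:
#' deletion-type (`+/-`), duplication-type (`-/+`), and the two inversion
#' types, head-to-head (`+/+`) and tail-to-tail (`-/-`).  The class is a
#' pure function of the strand pair.
#'
#' @param strand1,strand2 character vectors of "+"/"-".
#' @return character vector in `c("del", "dup", "inv_head", "inv_tail")`.
#' @export
orientation_class <- function(strand1, strand2) {
  key <- paste0(strand1, strand2)
  map <- c("+-" = "del", "-+" = "dup", "++" = "inv_head", "--" = "inv_tail")
  out <- unname(map[key])
  if (anyNA(out)) stop("invalid strand pair: ", key[which(is.na(out))[1]])
  out
}

#' Levels of the join orientation class
#' @return character vector of the four class labels.
#' @export
orientation_levels <- function() c("del", "dup", "inv_head", "inv_tail")

#' Read structural-variant breakpoint pairs from a BEDPE file
#'
#' Standard BEDPE: chrom1, start1, end1, chrom2, start2, end2, name, score,
#' strand1, strand2 (0-based half-open; the breakend position is taken as
#' the interval start).  Strand columns are mandatory because the join
#' orientation class is derived from them.
#'
#' @param path BEDPE file path.
#' @return data frame with columns `chrom1`, `pos1`, `strand1`, `chrom2`,
#'   `pos2`, `strand2`, `name`, `orientation`.
#' @seealso [write_bedpe()]
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop("BEDPE file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (nrow(df) && ncol(df) < 10) {
    stop("BEDPE file must have 10 columns incl. strand1/strand2: ", path)
  }
  if (!nrow(df)) {
    return(empty_joins())
  }
  out <- data.frame(chrom1 = normalize_chrom(df[[1]]),
                    pos1 = as.numeric(df[[2]]),
                    strand1 = as.character(df[[9]]),
                    chrom2 = normalize_chrom(df[[4]]),
                    pos2 = as.numeric(df[[5]]),
                    strand2 = as.character(df[[10]]),
                    name = as.character(df[[7]]),
                    stringsAsFactors = FALSE)
  out$orientation <- orientation_class(out$strand1, out$strand2)
  out
}

empty_joins <- function() {
  data.frame(chrom1 = character(), pos1 = numeric(), strand1 = character(),
             chrom2 = character(), pos2 = numeric(), strand2 = character(),
             name = character(), orientation = character(),
             stringsAsFactors = FALSE)
}

#' Write breakpoint joins as BEDPE
#'
#' Each breakend is written as a 1-bp interval `[pos, pos + 1)`.
#'
#' @param joins data frame as returned by [read_bedpe()].
#' @param path output path.
#' @export
write_bedpe <- function(joins, path) {
  n <- nrow(joins)
  nm <- if (n && !is.null(joins$name)) joins$name else if (n) sprintf("join%d", seq_len(n)) else character()
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  df <- data.frame(joins$chrom1, fmt(joins$pos1), fmt(joins$pos1 + 1),
                   joins$chrom2, fmt(joins$pos2), fmt(joins$pos2 + 1),
                   nm, rep(".", n), joins$strand1, joins$strand2)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read small-variant calls from a VCF 4.2 file
#'
#' Reads the restricted VCF dialect emitted by [write_vcf()] and by common
#' small-variant callers: single sample, QUAL column populated or ".", and
#' an allele-depth source naming either a per-sample `AD`-style FORMAT
#' field (`dialect = "AD"`, default: ref depth then one value per ALT) or
#' two INFO counts (`dialect = "INFO"`, fields `DP` and `AC` read as total
#' and alt depth).  Multi-allelic records are decomposed into one row per
#' ALT allele.
#'
#' @param path VCF file path.
#' @param dialect `"AD"` or `"INFO"` (allele-depth source).
#' @return data frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `qual` (NA when "."), `alt_reads`, `total_depth`, `vaf`, `compartment`,
#'   `coding`.  `compartment` and `coding` come from the INFO fields
#'   `COMPARTMENT` and `CODING` when present (else `NA`/`FALSE`).
#' @export
read_vcf <- function(path, dialect = c("AD", "INFO")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("VCF file not found: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(empty_variants())
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 8)) stop("malformed VCF record at data line ", which(ncols < 8)[1])
  rows <- lapply(fields, function(f) parse_vcf_record(f, dialect))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_variants <- function() {
  data.frame(chrom = character(), pos = numeric(), ref = character(),
             alt = character(), qual = numeric(), alt_reads = numeric(),
             total_depth = numeric(), vaf = numeric(),
             compartment = character(), coding = logical(),
             stringsAsFactors = FALSE)
}

parse_info <- function(info) {
  if (identical(info, ".")) return(character())
  kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- vapply(kv, function(p) if (length(p) > 1) p[2] else "TRUE", "")
  names(vals) <- vapply(kv, `[[`, "", 1)
  vals
}

parse_vcf_record <- function(f, dialect) {
  alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
  n_alt <- length(alts)
  qual <- if (identical(f[6], ".")) NA_real_ else as.numeric(f[6])
  info <- parse_info(f[8])
  if (dialect == "AD") {
    if (length(f) < 10) stop("dialect 'AD' requires a sample column in the VCF")
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    smp <- strsplit(f[10], ":", fixed = TRUE)[[1]]
    ad_i <- match("AD", fmt)
    if (is.na(ad_i)) stop("allele-depth field 'AD' absent from FORMAT")
    ad <- as.numeric(strsplit(smp[ad_i], ",", fixed = TRUE)[[1]])
    if (length(ad) != n_alt + 1) stop("AD length does not match ALT count")
    total <- sum(ad)
    alt_reads <- ad[-1]
  } else {
    if (!all(c("DP", "AC") %in% names(info))) {
      stop("dialect 'INFO' requires INFO fields DP and AC")
    }
    total <- as.numeric(info[["DP"]])
    ac <- as.numeric(strsplit(info[["AC"]], ",", fixed = TRUE)[[1]])
    if (length(ac) == 1) ac <- rep(ac, n_alt)
    alt_reads <- ac
  }
  compartment <- if ("COMPARTMENT" %in% names(info)) info[["COMPARTMENT"]] else NA_character_
  coding <- "CODING" %in% names(info) && !identical(info[["CODING"]], "0")
  data.frame(chrom = normalize_chrom(f[1]), pos = as.numeric(f[2]),
             ref = f[4], alt = alts, qual = qual,
             alt_reads = alt_reads, total_depth = total,
             vaf = ifelse(total > 0, alt_reads / total, NA_real_),
             compartment = compartment, coding = coding,
             stringsAsFactors = FALSE)
}

#' Write variant calls as a minimal VCF 4.2 file
#'
#' One record per variant (no multi-allelic merging on write), QUAL from
#' `qual` (NA written as "."), allele depths in the sample `AD` field, and
#' `COMPARTMENT`/`CODING` stored as INFO fields so the compartment label
#' survives a round trip.
#'
#' @param variants data frame as returned by [read_vcf()].
#' @param path output path.
#' @param sample_name sample column header.
#' @export
write_vcf <- function(variants, path, sample_name = "SAMPLE") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=COMPARTMENT,Number=1,Type=String,Description=\"germline or somatic\">",
    "##INFO=<ID=CODING,Number=1,Type=Integer,Description=\"1 if coding\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  n <- nrow(variants)
  if (n) {
    o <- order(variants$chrom, variants$pos)
    v <- variants[o, ]
    qual <- ifelse(is.na(v$qual), ".", format(v$qual, trim = TRUE))
    info <- sprintf("COMPARTMENT=%s;CODING=%d",
                    ifelse(is.na(v$compartment), ".", v$compartment),
                    as.integer(v$coding))
    ad <- sprintf("%d,%d", as.integer(v$total_depth - v$alt_reads),
                  as.integer(v$alt_reads))
    recs <- paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE),
                  ".", v$ref, v$alt, qual, "PASS", info, "AD", ad, sep = "\t")
  } else {
    recs <- character()
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a clinical table (Table-1 dialect)
#'
#' Tab-separated with columns `id`, `age`, `histology`, `dose_gy`, `field`,
#' `latency_y`, `status`, `survival_months`.  A dash (`-` or the typographic
#' en dash) or an empty cell marks a missing value.  Numeric columns are
#' parsed to numeric with missing as `NA`; `status` is mapped to
#' `"deceased"` (from `D`/`deceased`) or `"unknown"`.
#'
#' @param path clinical TSV path.
#' @return data frame of clinical records.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("id", "age", "histology", "dose_gy", "field", "latency_y",
                "status", "survival_months")
  if (!all(required %in% names(df))) {
    stop("clinical table must have columns: ", paste(required, collapse = ", "))
  }
  miss <- function(x) {
    x <- trimws(x)
    x[x %in% c("-", "–", "—", "", "NA")] <- NA
    x
  }
  num <- function(x) suppressWarnings(as.numeric(miss(x)))
  status <- miss(df$status)
  status <- ifelse(is.na(status), "unknown",
                   ifelse(toupper(status) %in% c("D", "DECEASED"), "deceased", "unknown"))
  data.frame(id = df$id,
             age = num(df$age),
             histology = miss(df$histology),
             dose_gy = miss(df$dose_gy),  # kept as text: multi-course doses like "23.4, 54"
             field = miss(df$field),
             latency_y = num(df$latency_y),
             status = status,
             survival_months = num(df$survival_months),
             stringsAsFactors = FALSE)
}

#' Write a clinical table in the Table-1 dialect
#'
#' @param clinical data frame as returned by [read_clinical()].
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) {
  df <- clinical
  df$status <- ifelse(df$status == "deceased", "D", "-")
  for (col in names(df)) {
    x <- as.character(df[[col]])
    x[is.na(x)] <- "-"
    df[[col]] <- x
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The bundled clinical summary table of the RIG cohort
#'
#' The printed per-case clinical summary (age at first cancer, first-cancer
#' histology, radiation dose and field, latency to RIG, vital status) used
#' by the cohort-statistics worked examples and the acceptance checks.
#'
#' @return clinical data frame (see [read_clinical()]).
#' @examples
#' cl <- rig_clinical_table()
#' median_and_range(cl$age)
#' @export
rig_clinical_table <- function() {
  read_clinical(system.file("extdata", "table1_clinical.tsv",
                            package = "rigstruct"))
}
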