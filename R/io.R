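# io_formats: every external file the pipeline touches, read and written
# through validated, bit-faithful helpers. FASTA goes through Biostrings;
# tables are strict TSV (no quoting, "." decimal) so fixtures stay diffable.

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are normalised to DNA uppercase (`U` is converted to `T`) so the
#' rest of the pipeline works on a single alphabet; RNA input (e.g. mature
#' miRNA FASTA from miRBase) is therefore accepted. The record id is the first
#' whitespace-delimited token of the header; the remainder is retained as a
#' description.
#'
#' @param path path to a FASTA file with at least one record.
#' @return a `data.frame` with columns `id`, `seq` (DNA uppercase) and `desc`,
#'   in file order.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">m1 some miRNA", "UAAGG"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("FASTA record with empty id", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id: '", dup[1], "'", call. = FALSE)
  }
  seqs <- normalize_seq(as.character(set))
  check_alphabet(seqs, ids)
  data.frame(id = ids, seq = unname(seqs), desc = unname(desc),
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: `write_fasta(read_fasta(f))` reproduces ids and
#' (normalised) sequences exactly.
#'
#' @param records data.frame with columns `id`, `seq` and optionally `desc`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  seqs <- Biostrings::DNAStringSet(normalize_seq(records$seq))
  desc <- if ("desc" %in% names(records)) records$desc else
    character(nrow(records))
  names(seqs) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read a small-RNA read-count table
#'
#' Expects a strict TSV whose first column holds miRNA names and whose
#' remaining columns are libraries named `IP_<r>` / `TOTAL_<r>`. Every IP
#' replicate must be paired with a TOTAL replicate of the same index, matching
#' the paired IP/input design of miRISC co-immunoprecipitation experiments.
#'
#' @param path path to the TSV (lines starting with `#` are ignored).
#' @return an integer matrix (miRNA x library) of class `mirna_counts`, with
#'   attribute `replicates` giving the paired replicate indices.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("count table needs a name column and >=2 libraries",
                          call. = FALSE)
  libs <- names(df)[-1]
  ok <- grepl("^(IP|TOTAL)_[0-9]+$", libs)
  if (any(!ok)) stop("bad library name(s): ", paste(libs[!ok], collapse = ", "),
                     "; expected IP_<r> / TOTAL_<r>", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  bad <- which(is.na(m) | m < 0 | m %% 1 != 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-count cell at row '%s', column '%s'",
                 rownames(m)[bad[1, 1]], libs[bad[1, 2]]), call. = FALSE)
  }
  mirna_counts(m)
}

#' Construct a `mirna_counts` matrix
#'
#' @param m numeric matrix of non-negative integer read counts with miRNA row
#'   names and `IP_<r>` / `TOTAL_<r>` column names.
#' @return the validated matrix with class `mirna_counts`.
#' @export
mirna_counts <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  libs <- colnames(m)
  frac <- sub("_.*$", "", libs)
  rep_id <- as.integer(sub("^.*_", "", libs))
  ip_reps <- sort(rep_id[frac == "IP"])
  tot_reps <- sort(rep_id[frac == "TOTAL"])
  if (!identical(ip_reps, tot_reps)) {
    stop(sprintf("unpaired replicates: IP has {%s}, TOTAL has {%s}",
                 paste(ip_reps, collapse = ","),
                 paste(tot_reps, collapse = ",")), call. = FALSE)
  }
  if (length(ip_reps) < 1L) stop("no replicates found", call. = FALSE)
  storage.mode(m) <- "double"
  structure(m, class = c("mirna_counts", class(m)),
            replicates = ip_reps)
}

#' @export
print.mirna_counts <- function(x, ...) {
  cat(sprintf("miRNA read-count table: %d miRNAs x %d libraries (%d paired replicates)\n",
              nrow(x), ncol(x), length(attr(x, "replicates"))))
  print(utils::head(unclass(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("... (%d more rows)\n", nrow(x) - 6L))
  invisible(x)
}

#' Write a read-count table as strict TSV
#'
#' @param counts a `mirna_counts` matrix.
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, seed = NULL) {
  df <- data.frame(mirna = rownames(counts), unclass(counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_report(df, path, seed = seed)
}

#' Read a named gene set
#'
#' One gene identifier per line; blank lines and `#` comments are ignored;
#' duplicates are dropped (and counted in a log message).
#'
#' @param path path to the list file.
#' @param name name of the set (defaults to the file name).
#' @return an object of class `gene_set`: a list with `name` and a character
#'   vector `members`.
#' @export
read_gene_set <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  members <- unique(lines)
  ndup <- length(lines) - length(members)
  if (ndup > 0L) log_msg("io", "gene set '%s': dropped %d duplicate id(s)",
                         name, ndup)
  if (length(members) == 0L) {
    stop("gene set '", name, "' is empty after filtering", call. = FALSE)
  }
  gene_set(name, members)
}

#' Construct a gene set
#'
#' @param name non-empty set name.
#' @param members character vector of gene ids (deduplicated).
#' @return a `gene_set` object.
#' @export
gene_set <- function(name, members) {
  stopifnot(is.character(name), nzchar(name))
  members <- unique(as.character(members))
  structure(list(name = name, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene set '%s': %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' Construct a probe-level microarray signal container
#'
#' Holds probe-level IP and Total signals plus per-replicate detection flags,
#' with the probe -> transcript -> gene map and a platform label per replicate
#' column. Probes not measured on a platform carry `NA` signal and `FALSE`
#' detection in that platform's columns.
#'
#' @param info data.frame with columns `probe`, `transcript`, `gene` (one row
#'   per probe; each probe maps to exactly one transcript).
#' @param ip,total numeric probe x replicate matrices of signals.
#' @param det_ip,det_total logical probe x replicate detection ("reliable
#'   signal") flags.
#' @param platform character vector, one platform label per replicate column.
#' @return an object of class `probe_signal`.
#' @export
probe_signal <- function(info, ip, total, det_ip, det_total, platform) {
  stopifnot(is.data.frame(info),
            all(c("probe", "transcript", "gene") %in% names(info)),
            nrow(info) == nrow(ip),
            identical(dim(ip), dim(total)),
            identical(dim(ip), dim(det_ip)),
            identical(dim(ip), dim(det_total)),
            length(platform) == ncol(ip))
  if (anyDuplicated(info$probe)) {
    stop("duplicate probe id: '", info$probe[duplicated(info$probe)][1], "'",
         call. = FALSE)
  }
  rownames(info) <- NULL
  det_ip[is.na(ip)] <- FALSE
  det_total[is.na(total)] <- FALSE
  structure(list(info = info, ip = ip, total = total,
                 det_ip = det_ip, det_total = det_total,
                 platform = as.character(platform)),
            class = "probe_signal")
}

#' @export
print.probe_signal <- function(x, ...) {
  cat(sprintf("probe signal table: %d probes, %d genes, %d replicates (platforms: %s)\n",
              nrow(x$info), length(unique(x$info$gene)), ncol(x$ip),
              paste(unique(x$platform), collapse = ", ")))
  invisible(x)
}

#' Write a probe signal table as wide TSV
#'
#' Columns: `probe`, `transcript`, `gene`, then per replicate `IP_<r>`,
#' `TOTAL_<r>`, `DET_IP_<r>`, `DET_TOTAL_<r>`. Replicate platforms are stored
#' in a `#platforms:` header line so the file round-trips.
#'
#' @param ps a `probe_signal` object.
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(ps, path, seed = NULL) {
  nrep <- ncol(ps$ip)
  df <- ps$info[, c("probe", "transcript", "gene")]
  for (r in seq_len(nrep)) {
    df[[sprintf("IP_%d", r)]] <- ps$ip[, r]
    df[[sprintf("TOTAL_%d", r)]] <- ps$total[, r]
    df[[sprintf("DET_IP_%d", r)]] <- as.integer(ps$det_ip[, r])
    df[[sprintf("DET_TOTAL_%d", r)]] <- as.integer(ps$det_total[, r])
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_line(seed = seed), con)
  writeLines(paste0("#platforms: ", paste(ps$platform, collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe signal table written by [write_probe_table()]
#'
#' @param path path to the wide TSV.
#' @return a `probe_signal` object.
#' @export
read_probe_table <- function(path) {
  head_lines <- readLines(path, n = 10L)
  plat_line <- grep("^#platforms:", head_lines, value = TRUE)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  rep_cols <- grep("^IP_[0-9]+$", names(df), value = TRUE)
  nrep <- length(rep_cols)
  if (nrep < 1L) stop("no IP_<r> columns found", call. = FALSE)
  get <- function(prefix, mode) {
    m <- as.matrix(df[, sprintf("%s_%d", prefix, seq_len(nrep)), drop = FALSE])
    colnames(m) <- sprintf("R%d", seq_len(nrep))
    if (mode == "logical") m <- m == 1L
    m
  }
  platform <- if (length(plat_line)) {
    strsplit(sub("^#platforms:\\s*", "", plat_line[1]), ",")[[1]]
  } else rep("P1", nrep)
  probe_signal(df[, c("probe", "transcript", "gene")],
               ip = get("IP", "numeric"), total = get("TOTAL", "numeric"),
               det_ip = get("DET_IP", "logical"),
               det_total = get("DET_TOTAL", "logical"),
               platform = platform)
}
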