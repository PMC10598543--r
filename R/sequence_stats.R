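#' @useDynLib linkersim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef lm nls optim optimize rnorm runif sd setNames weighted.mean
#' @importFrom utils read.delim write.table head tail
NULL

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty character scalar")
  letters <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(letters), AA_ALPHABET)
  if (length(bad))
    stop("non-canonical residue letter(s): ", paste(bad, collapse = ", "))
  letters
}

#' Linker record
#'
#' A linker sequence with its provenance: the parent protein identifier and
#' the 1-based inclusive residue range the linker occupies in the parent.
#'
#' @param id identifier for the linker.
#' @param parent_id identifier of the parent protein.
#' @param sequence amino-acid sequence (uppercase, 20 canonical letters).
#' @param start_res,end_res 1-based inclusive residue indices in the parent.
#' @return An object of class `linker_record`.
#' @export
linker_record <- function(id, parent_id, sequence, start_res, end_res) {
  letters <- check_sequence(sequence)
  start_res <- as.integer(start_res); end_res <- as.integer(end_res)
  if (end_res - start_res + 1L != length(letters))
    stop("sequence length does not match residue range ", start_res, "-", end_res)
  structure(list(id = id, parent_id = parent_id, sequence = sequence,
                 start_res = start_res, end_res = end_res),
            class = "linker_record")
}

#' @export
print.linker_record <- function(x, ...) {
  cat(sprintf("<linker_record> %s (parent %s), residues %d-%d, N = %d\n",
              x$id, x$parent_id, x$start_res, x$end_res, nchar(x$sequence)))
  cat(" ", x$sequence, "\n")
  invisible(x)
}

#' Extract the interdomain linker from a two-domain parent
#'
#' Given a parent sequence annotated with exactly two non-overlapping folded
#' domains (the AA10-linker-CBM2 architecture of modular LPMOs), returns the
#' residues strictly between the first domain's end and the second domain's
#' start as a [linker_record]. Coordinates follow the UniProt convention:
#' 1-based, inclusive.
#'
#' @param parent_sequence full-length amino-acid sequence of the parent.
#' @param annotations a data.frame with columns `parent_id`, `domain_name`,
#'   `start_res`, `end_res` (see [read_domain_annotations]) containing the
#'   rows for this parent.
#' @param parent_id identifier recorded in the returned record.
#' @return A [linker_record] spanning (end of domain 1)+1 .. (start of
#'   domain 2)-1.
#' @examples
#' seq <- paste(rep("A", 12), collapse = "")
#' ann <- data.frame(parent_id = "p", domain_name = c("AA10", "CBM2"),
#'                   start_res = c(1, 10), end_res = c(5, 12))
#' extract_linker(seq, ann)  # residues 6-9
#' @export
extract_linker <- function(parent_sequence, annotations, parent_id = "parent") {
  check_sequence(parent_sequence)
  if (!all(c("start_res", "end_res") %in% names(annotations)))
    stop("annotations must have start_res and end_res columns")
  if (nrow(annotations) != 2L)
    stop("unsupported architecture: expected exactly 2 domains, got ",
         nrow(annotations))
  ann <- annotations[order(annotations$start_res), , drop = FALSE]
  if (any(ann$start_res > ann$end_res))
    stop("domain with start_res > end_res")
  if (ann$end_res[1] >= ann$start_res[2])
    stop("overlapping domains: ", ann$end_res[1], " >= ", ann$start_res[2])
  lo <- ann$end_res[1] + 1L
  hi <- ann$start_res[2] - 1L
  if (lo > hi)
    stop("empty linker: domains at ", ann$end_res[1], " and ",
         ann$start_res[2], " are adjacent")
  if (hi > nchar(parent_sequence))
    stop("domain coordinates exceed parent length")
  linker_record(id = paste0(parent_id, "_linker"), parent_id = parent_id,
                sequence = substr(parent_sequence, lo, hi),
                start_res = lo, end_res = hi)
}

#' Compositional descriptors of a linker
#'
#' Computes the descriptors used to characterise LPMO linkers: length N, net
#' charge per residue (NCPR, counting K/R as +1 and D/E as -1), the fraction
#' of residues predicted to contribute to chain expansion (E, D, R, K, P),
#' the proline fraction, and the full amino-acid frequency table. Histidine
#' is counted as uncharged.
#'
#' @param linker a [linker_record], or a plain sequence string.
#' @return An object of class `composition_stats` with fields `n_residues`,
#'   `ncpr`, `fraction_expanding`, `fraction_proline`, `aa_frequencies`.
#' @examples
#' compute_composition("DKPE")  # ncpr -0.25, expanding 1, proline 0.25
#' @export
compute_composition <- function(linker) {
  sequence <- if (inherits(linker, "linker_record")) linker$sequence else linker
  letters <- check_sequence(sequence)
  n <- length(letters)
  counts <- table(factor(letters, levels = AA_ALPHABET))
  cnt <- function(aa) sum(counts[aa])
  ncpr <- (cnt("K") + cnt("R") - cnt("D") - cnt("E")) / n
  structure(list(
    n_residues = n,
    ncpr = ncpr,
    fraction_expanding = cnt(c("E", "D", "R", "K", "P")) / n,
    fraction_proline = cnt("P") / n,
    aa_frequencies = setNames(as.numeric(counts) / n, AA_ALPHABET)
  ), class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf(
    "<composition_stats> N = %d, NCPR = %.2f, expanding = %.2f, Pro = %.2f\n",
    x$n_residues, x$ncpr, x$fraction_expanding, x$fraction_proline))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta_sequences <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta_sequences <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Read a domain-annotation TSV
#'
#' Expects a header line with columns `parent_id`, `domain_name`,
#' `start_res`, `end_res`; coordinates are 1-based inclusive.
#'
#' @param path TSV file.
#' @return data.frame with those four columns.
#' @export
read_domain_annotations <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("parent_id", "domain_name", "start_res", "end_res")
  if (!all(need %in% names(ann)))
    stop("domain TSV must have header columns: ", paste(need, collapse = ", "))
  ann$start_res <- as.integer(ann$start_res)
  ann$end_res <- as.integer(ann$end_res)
  ann
}

#' Survey linkers across a set of two-domain parents
#'
#' Runs [extract_linker] + [compute_composition] for every parent present in
#' the annotation table. Parents failing the architecture checks (more or
#' fewer than two domains, adjacent or overlapping domains) are skipped with
#' a warning and reported in the `skipped` attribute.
#'
#' @param sequences named character vector of parent sequences (e.g. from
#'   [read_fasta_sequences]).
#' @param annotations data.frame from [read_domain_annotations].
#' @return data.frame with one row per surveyed linker: `id`, `parent_id`,
#'   `n_residues`, `ncpr`, `fraction_expanding`, `fraction_proline`,
#'   `start_res`, `end_res`, `sequence`.
#' @export
survey_linkers <- function(sequences, annotations) {
  parents <- unique(annotations$parent_id)
  rows <- list(); skipped <- character()
  for (p in parents) {
    ann <- annotations[annotations$parent_id == p, , drop = FALSE]
    if (!p %in% names(sequences)) {
      warning("no sequence for parent ", p, "; skipped")
      skipped <- c(skipped, p); next
    }
    rec <- tryCatch(extract_linker(sequences[[p]], ann, parent_id = p),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      warning("parent ", p, " skipped: ", conditionMessage(rec))
      skipped <- c(skipped, p); next
    }
    cs <- compute_composition(rec)
    rows[[p]] <- data.frame(
      id = rec$id, parent_id = p, n_residues = cs$n_residues,
      ncpr = cs$ncpr, fraction_expanding = cs$fraction_expanding,
      fraction_proline = cs$fraction_proline,
      start_res = rec$start_res, end_res = rec$end_res,
      sequence = rec$sequence, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), parent_id = character(),
               n_residues = integer(), ncpr = numeric(),
               fraction_expanding = numeric(), fraction_proline = numeric(),
               start_res = integer(), end_res = integer(),
               sequence = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write a descriptor table as TSV
#'
#' Numeric descriptor columns are rounded to 2 decimals for display parity
#' with reference tables; full precision is available from [survey_linkers].
#'
#' @param descriptors data.frame from [survey_linkers].
#' @param path output TSV.
#' @export
write_descriptor_tsv <- function(descriptors, path) {
  out <- descriptors
  for (cl in c("ncpr", "fraction_expanding", "fraction_proline"))
    if (cl %in% names(out)) out[[cl]] <- round(out[[cl]], 2)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
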