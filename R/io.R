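## FASTA input and TSV report output.

#' Read a FASTA file of nucleotide sequences
#'
#' Wrapped lines are joined; ids are the first whitespace-delimited token
#' of each header; U is normalised to T and lowercase is uppercased.
#' Records containing IUPAC ambiguity codes (including N) or no sequence
#' at all are rejected with the offending record named: the pentamer
#' statistics have no defined behaviour for ambiguous bases.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector over `{A,C,G,T}`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("malformed FASTA '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  if (length(set) == 0L) stop(sprintf("empty FASTA: %s", path), call. = FALSE)
  seqs <- as.character(set)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  names(seqs) <- ids
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    stop(sprintf("record '%s' in %s has no sequence", ids[empty][1L], path),
         call. = FALSE)
  }
  normalize_nt(seqs, what = "record")
}

#' Write PpAL results as a TSV report
#'
#' One row per scored sequence; numeric columns are rendered at a
#' configurable precision (sigma-unit quantities to `digits` decimals,
#' expectations to 2 significant figures, matching the conventional
#' display). Machine-readable: no sigma suffixes.
#'
#' @param rows A data.frame with columns `id`, `species`, `molecule` and a
#'   list-column or separate columns of the `ppal_result` fields, or a
#'   list of `ppal_result` objects named by id.
#' @param path Output path.
#' @param digits Decimals for `p_al` / `Pp_al` (default 1).
#' @return The path, invisibly.
#' @export
write_report <- function(rows, path, digits = 1L) {
  df <- ppal_table(rows)
  out <- data.frame(
    id = df$id, species = df$species, molecule = df$molecule,
    N = df$N, n_o = df$n_o,
    n_e = signif(df$n_e, 2), sigma = signif(df$sigma_e, 2),
    p_al = round(df$p_al, digits), Pp_al = round(df$Pp_al, digits)
  )
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop(sprintf("cannot write '%s'", path),
                                           call. = FALSE))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a data.frame of PpAL results
#'
#' @param rows A list of `ppal_result` objects (optionally named by id) or
#'   a data.frame already carrying the result fields (passed through, with
#'   missing `id`/`species`/`molecule` columns filled with `NA`).
#' @return A data.frame with columns `id`, `species`, `molecule`, `N`,
#'   `n_o`, `n_e`, `sigma_e`, `p_al`, `Pp_al`.
#' @export
ppal_table <- function(rows) {
  if (is.data.frame(rows)) {
    df <- rows
  } else {
    stopifnot(length(rows) >= 0L)
    ids <- if (!is.null(names(rows))) names(rows) else as.character(seq_along(rows))
    df <- do.call(rbind, lapply(seq_along(rows), function(i) {
      r <- rows[[i]]
      stopifnot(inherits(r, "ppal_result"))
      data.frame(id = ids[i], N = r$N, n_o = r$n_o, n_e = r$n_e,
                 sigma_e = r$sigma_e, p_al = r$p_al, Pp_al = r$Pp_al)
    }))
    if (is.null(df)) {
      df <- data.frame(id = character(0), N = integer(0), n_o = integer(0),
                       n_e = numeric(0), sigma_e = numeric(0),
                       p_al = numeric(0), Pp_al = numeric(0))
    }
  }
  for (col in c("id", "species", "molecule")) {
    if (is.null(df[[col]])) df[[col]] <- rep(NA_character_, nrow(df))
  }
  df[, c("id", "species", "molecule", "N", "n_o", "n_e", "sigma_e",
         "p_al", "Pp_al"), drop = FALSE]
}

#' Reference PpAL table for four species
#'
#' The packaged reference table of observed pentamer counts `n_o` and
#' sequence lengths `N` for eight molecule families across Homo sapiens
#' (HS), Saccharomyces cerevisiae (SC), Methanococcus voltae (Mv) and a
#' Methanococcus isolate (Mmi), together with the published proximity
#' values (`Pp_al_ref`, `p_al_ref`, `mean_Pp_al_ref` per molecule), used
#' by the worked examples and the conformance tests.
#'
#' @return A data.frame with columns `molecule`, `species`, `n_o`, `N`,
#'   `Pp_al_ref`, `p_al_ref`, `mean_Pp_al_ref`.
#' @export
ppal_reference <- function() {
  path <- system.file("extdata", "ppal_reference.tsv", package = "alring",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
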