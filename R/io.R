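FORMAT_VERSION <- "1"

#' Read protein sequences from FASTA
#'
#' Parses a (possibly gzipped) FASTA file, preserving record order, and
#' validates that every sequence uses only the 20 standard residues.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(aas))
  seqs <- as.character(aas)
  for (i in seq_along(seqs)) {
    bad <- setdiff(strsplit(seqs[i], "")[[1]], AA_STANDARD)
    if (length(bad) > 0L)
      stop("record ", ids[i], ": non-standard residue(s) ",
           paste(bad, collapse = ","), call. = FALSE)
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Serialize a proteome model to JSON
#'
#' Writes the full model (proteins, scheme, string universe as compact
#' label keys, sparse conditional matrix as per-protein index/value pairs,
#' expected observable-string counts) with full floating-point precision.
#'
#' @param model a `proteome_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- list(
    format_version = FORMAT_VERSION,
    dud_rate = model$dud_rate,
    scheme = list(channels = model$scheme$channels,
                  protease = model$scheme$protease),
    proteins = model$proteins,
    peptide_counts = model$peptide_counts,
    strings = vapply(model$strings, function(f) f$key, character(1)),
    e_fo = model$e_fo,
    cond = lapply(seq_len(nrow(model$cond_FI)), function(y) {
      j <- model$support[[y]]
      list(j = j, x = as.numeric(model$cond_FI[y, j]))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a proteome model from JSON
#'
#' @param path a file written by [write_model()].
#' @return A `proteome_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(as.character(doc$format_version), FORMAT_VERSION))
    stop("model schema version mismatch: ", doc$format_version,
         call. = FALSE)
  scheme <- label_scheme(
    channels = lapply(doc$scheme$channels, function(x) unlist(x)),
    protease = doc$scheme$protease)
  keys <- vapply(doc$strings, identity, character(1))
  strings <- lapply(keys, function(k) {
    labels <- if (nzchar(k)) as.integer(strsplit(k, ".", fixed = TRUE)[[1]])
              else integer(0)
    fluorescence_string(labels, scheme$n_channels)
  })
  proteins <- data.frame(
    id = vapply(doc$proteins, function(p) p$id, character(1)),
    sequence = vapply(doc$proteins, function(p) p$sequence, character(1)),
    stringsAsFactors = FALSE)
  n_p <- nrow(proteins)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (y in seq_len(n_p)) {
    j <- as.integer(unlist(doc$cond[[y]]$j))
    x <- as.numeric(unlist(doc$cond[[y]]$x))
    ii <- c(ii, rep.int(y, length(j))); jj <- c(jj, j); xx <- c(xx, x)
  }
  cond_FI <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                  dims = c(n_p, length(keys)),
                                  dimnames = list(proteins$id, NULL))
  support <- lapply(seq_len(n_p), function(y) sort(jj[ii == y]))
  structure(
    list(proteins = proteins, strings = strings, cond_FI = cond_FI,
         e_fo = as.numeric(unlist(doc$e_fo)), support = support,
         scheme = scheme, dud_rate = doc$dud_rate,
         peptide_counts = as.integer(unlist(doc$peptide_counts))),
    class = "proteome_model"
  )
}

#' Per-protein digestion/observability report
#'
#' @param model a `proteome_model`.
#' @return data.frame with per-protein peptide counts, observable-string
#'   counts and expected observable strings per molecule.
#' @export
model_report <- function(model) {
  data.frame(
    id = model$proteins$id,
    n_peptides = model$peptide_counts,
    n_observable_strings = vapply(model$support, length, integer(1)),
    e_fo = model$e_fo,
    stringsAsFactors = FALSE
  )
}

#' Write simulated reads (and truth) as TSV
#'
#' Reads go to `<prefix>_reads.tsv` (read_id, then channel-major intensity
#' columns `c<ch>_t<t>`), truth to `<prefix>_truth.tsv` (read_id,
#' true_string, true_protein), and run metadata (seed, error model) to
#' `<prefix>_meta.json`.
#'
#' @param dataset a `fluor_dataset` with intensities.
#' @param prefix output path prefix.
#' @return The three file paths, invisibly.
#' @export
write_dataset <- function(dataset, prefix) {
  stopifnot(!is.null(dataset$intensities))
  dims <- dim(dataset$intensities)
  n_ch <- dims[1]; n_t <- dims[2]; n <- dims[3]
  flat <- matrix(aperm(dataset$intensities, c(3L, 1L, 2L)), nrow = n)
  cols <- as.vector(outer(seq_len(n_ch), seq_len(n_t),
                          function(c, t) paste0("c", c, "_t", t)))
  flat_df <- as.data.frame(flat)
  names(flat_df) <- cols
  dt <- cbind(data.frame(read_id = seq_len(n)), flat_df)
  reads_path <- paste0(prefix, "_reads.tsv")
  truth_path <- paste0(prefix, "_truth.tsv")
  meta_path <- paste0(prefix, "_meta.json")
  data.table::fwrite(dt, reads_path, sep = "\t")
  data.table::fwrite(
    data.table::data.table(read_id = seq_len(n),
                           true_string = dataset$true_string,
                           true_protein = dataset$true_protein),
    truth_path, sep = "\t")
  jsonlite::write_json(
    list(format_version = FORMAT_VERSION, seed = dataset$seed,
         n_reads = n, n_rejected = dataset$n_rejected,
         error_model = unclass(dataset$error_model),
         true_p = as.numeric(dataset$true_p)),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(reads_path, truth_path, meta_path))
}

#' Read a simulated dataset back from TSV
#'
#' @param prefix the prefix used by [write_dataset()].
#' @return A `fluor_dataset`.
#' @export
read_dataset <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  if (!identical(as.character(meta$format_version), FORMAT_VERSION))
    stop("dataset schema version mismatch", call. = FALSE)
  em <- do.call(error_model, meta$error_model[setdiff(
    names(meta$error_model), character(0))])
  reads <- data.table::fread(paste0(prefix, "_reads.tsv"), sep = "\t")
  truth <- data.table::fread(paste0(prefix, "_truth.tsv"), sep = "\t")
  n <- nrow(reads)
  cols <- setdiff(names(reads), "read_id")
  ch <- as.integer(sub("^c(\\d+)_t\\d+$", "\\1", cols))
  tt <- as.integer(sub("^c\\d+_t(\\d+)$", "\\1", cols))
  n_ch <- max(ch); n_t <- max(tt)
  inten <- array(NA_real_, dim = c(n_ch, n_t, n))
  for (i in seq_along(cols))
    inten[ch[i], tt[i], ] <- reads[[cols[i]]]
  structure(
    list(intensities = inten, true_string = truth$true_string,
         true_protein = truth$true_protein,
         true_p = abundance_vector(meta$true_p, "protein"),
         seed = meta$seed, error_model = em,
         n_rejected = meta$n_rejected),
    class = "fluor_dataset"
  )
}

#' Write sparse posteriors as TSV
#'
#' One row per read: read_id, then `n_b` (string index, probability) column
#' pairs `f<i>`/`p<i>`, then the per-string residual.
#'
#' @param posteriors a [sparse_posteriors()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_posteriors <- function(posteriors, path) {
  nb <- nrow(posteriors$top_index)
  n <- ncol(posteriors$top_index)
  dt <- data.table::data.table(
    read_id = if (is.null(posteriors$read_id)) seq_len(n)
              else posteriors$read_id)
  for (i in seq_len(nb)) {
    dt[[paste0("f", i)]] <- posteriors$top_index[i, ]
    dt[[paste0("p", i)]] <- posteriors$top_prob[i, ]
  }
  dt[["residual"]] <- posteriors$residual
  dt[["n_strings"]] <- posteriors$n_strings
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read sparse posteriors from TSV
#'
#' @param path a file written by [write_posteriors()].
#' @return A [sparse_posteriors()] object.
#' @export
read_posteriors <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  nb <- sum(grepl("^f\\d+$", names(dt)))
  top_index <- unname(t(as.matrix(dt[, paste0("f", seq_len(nb)),
                                     with = FALSE])))
  storage.mode(top_index) <- "integer"
  top_prob <- unname(t(as.matrix(dt[, paste0("p", seq_len(nb)),
                                    with = FALSE])))
  sparse_posteriors(top_index, top_prob, dt$residual,
                    dt$n_strings[1], dt$read_id)
}

#' Write an abundance vector as TSV
#' @param p protein- or indicator-space `abundance_vector` (or numeric).
#' @param path output path.
#' @param ids optional protein identifiers.
#' @return `path`, invisibly.
#' @export
write_abundances <- function(p, path, ids = NULL) {
  n <- length(p)
  data.table::fwrite(
    data.table::data.table(
      protein_id = if (is.null(ids)) seq_len(n) else ids,
      abundance = as.numeric(p),
      space = if (is.null(attr(p, "space"))) "protein" else attr(p, "space")),
    path, sep = "\t")
  invisible(path)
}

#' Read an abundance vector from TSV
#' @param path a file written by [write_abundances()].
#' @return An `abundance_vector`.
#' @export
read_abundances <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  abundance_vector(dt$abundance, dt$space[1])
}
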