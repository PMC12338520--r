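#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence into peptides. The built-in `"trypsin"` rule
#' cleaves C-terminal to lysine (K) or arginine (R) except when the next
#' residue is proline (P), with zero missed cleavages. Duplicate peptides are
#' retained with multiplicity: a peptide produced twice by a protein
#' contributes twice to the fluorescence-string frequencies.
#'
#' @param sequence amino-acid string over the 20 standard residues.
#' @param protease cleavage rule name; only `"trypsin"` is built in.
#' @return Character vector of peptides that partition `sequence` in order.
#' @examples
#' digest("AKRP")  # no cleavage after R because the next residue is P
#' @export
digest <- function(sequence, protease = "trypsin") {
  if (!identical(protease, "trypsin"))
    stop("unknown protease: ", protease, call. = FALSE)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  if (!all(aa %in% AA_STANDARD))
    stop("non-standard residue in sequence: ",
         paste(setdiff(aa, AA_STANDARD), collapse = ","), call. = FALSE)
  # cut after position i when aa[i] in {K,R} and aa[i+1] != P
  cuts <- which(aa[-n] %in% c("K", "R") & aa[-1] != "P")
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  vapply(seq_along(starts),
         function(i) paste(aa[starts[i]:ends[i]], collapse = ""),
         character(1))
}

#' Map a peptide to its fluorescence string
#'
#' Applies a labeling scheme positionally: position i carries the dye of
#' channel c iff the residue at i is one of channel c's targets. The result
#' is canonicalized by truncating after the last labeled position; peptides
#' with no labelable residue map to the null string `f_null`.
#'
#' @param peptide non-empty amino-acid string.
#' @param scheme a [label_scheme()].
#' @return A `fluorescence_string`: list with `labels` (integer vector, 0 =
#'   unlabeled, c = channel c, empty for `f_null`), `dye_count`,
#'   `per_channel_counts` and the canonical `key`.
#' @export
label_peptide <- function(peptide, scheme = label_scheme()) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  if (length(aa) == 0L) stop("empty peptide", call. = FALSE)
  labels <- integer(length(aa))
  for (c in seq_len(scheme$n_channels))
    labels[aa %in% scheme$channels[[c]]] <- c
  last <- if (any(labels > 0L)) max(which(labels > 0L)) else 0L
  fluorescence_string(labels[seq_len(last)], scheme$n_channels)
}

#' Construct a fluorescence string from label codes
#'
#' @param labels integer vector of per-position channel codes (0 =
#'   unlabeled); must be canonical (last entry labeled) or empty (`f_null`).
#' @param n_channels number of dye channels of the scheme.
#' @return A `fluorescence_string` object.
#' @export
fluorescence_string <- function(labels, n_channels) {
  labels <- as.integer(labels)
  if (length(labels) > 0L && labels[length(labels)] == 0L)
    stop("non-canonical fluorescence string: last position unlabeled",
         call. = FALSE)
  if (any(labels < 0L) || any(labels > n_channels))
    stop("label codes must be in 0..n_channels", call. = FALSE)
  per_channel <- tabulate(labels[labels > 0L], nbins = n_channels)
  structure(
    list(labels = labels,
         dye_count = sum(labels > 0L),
         per_channel_counts = per_channel,
         n_channels = as.integer(n_channels),
         key = paste(labels, collapse = ".")),
    class = "fluorescence_string"
  )
}

#' @export
print.fluorescence_string <- function(x, ...) {
  if (x$dye_count == 0L) cat("<f_null>\n")
  else cat("<fluorescence string ", x$key, ", ", x$dye_count, " dyes>\n",
           sep = "")
  invisible(x)
}

#' Observation probability of a fluorescence string
#'
#' A string with N_d ideally-labeled positions is experimentally observable
#' only if at least one of its dyes is functional. With per-dye dud rate `m`
#' this probability is `1 - m^N_d`; it is 0 for the null string (N_d = 0),
#' which is therefore never observed.
#'
#' @param f a `fluorescence_string`, or an integer dye count.
#' @param m per-dye dud (miss) rate, in `[0, 1)`.
#' @return Probability that at least one dye attaches and functions.
#' @export
observable_weight <- function(f, m) {
  if (!is.numeric(m) || m < 0 || m >= 1)
    stop("dud rate m must satisfy 0 <= m < 1", call. = FALSE)
  nd <- if (inherits(f, "fluorescence_string")) f$dye_count else as.integer(f)
  1 - m^nd
}

#' Build a fluorescence-string proteome model
#'
#' Digests and labels every protein, collects the universe `D_F` of distinct
#' fluorescence strings (the null string first), and computes for each
#' protein y the conditional distribution over observable strings
#' `P(f | I = y)` and the expected number of observable strings per molecule
#' `E_Fo(y)`. Each ideal string f_j from peptide j enters with weight
#' `w(f_j) = 1 - m^{N_d(f_j)}`; rows of the conditional matrix are these
#' weights normalized within a protein, so the null string always has
#' conditional probability 0.
#'
#' @param proteins data.frame with columns `id` and `sequence`, or a named
#'   character vector of sequences (see [read_fasta()]).
#' @param scheme a [label_scheme()].
#' @param m per-dye dud rate used for the observability reweighting.
#' @return An object of class `proteome_model`: `proteins`, `strings` (list
#'   of `fluorescence_string`, `f_null` at index 1), `cond_FI` (sparse
#'   proteins x strings matrix), `e_fo`, `support` (per-protein string index
#'   sets), `scheme`, `dud_rate`, `peptide_counts`.
#' @export
build_model <- function(proteins, scheme = label_scheme(), m = 0.07) {
  proteins <- as_protein_table(proteins)
  n_p <- nrow(proteins)

  string_index <- new.env(hash = TRUE, parent = emptyenv())
  strings <- list(fluorescence_string(integer(0), scheme$n_channels))
  assign("s", 1L, envir = string_index)  # env keys are "s" + label key

  ii <- jj <- integer(0)
  xx <- numeric(0)
  e_fo <- numeric(n_p)
  peptide_counts <- integer(n_p)

  for (y in seq_len(n_p)) {
    peps <- digest(proteins$sequence[y], scheme$protease)
    peptide_counts[y] <- length(peps)
    w_by_string <- new.env(hash = TRUE, parent = emptyenv())
    total <- 0
    for (pep in peps) {
      f <- label_peptide(pep, scheme)
      idx <- string_index[[paste0("s", f$key)]]
      if (is.null(idx)) {
        strings[[length(strings) + 1L]] <- f
        idx <- length(strings)
        assign(paste0("s", f$key), idx, envir = string_index)
      }
      w <- observable_weight(f, m)
      total <- total + w
      if (w > 0) {
        k <- as.character(idx)
        prev <- w_by_string[[k]]
        assign(k, if (is.null(prev)) w else prev + w, envir = w_by_string)
      }
    }
    e_fo[y] <- total
    if (total > 0) {
      ks <- ls(w_by_string)
      ii <- c(ii, rep.int(y, length(ks)))
      jj <- c(jj, as.integer(ks))
      xx <- c(xx, vapply(ks, function(k) w_by_string[[k]], numeric(1)) / total)
    }
  }

  if (all(e_fo == 0))
    stop("empty observable universe: no protein yields a labelable peptide",
         call. = FALSE)

  cond_FI <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                  dims = c(n_p, length(strings)),
                                  dimnames = list(proteins$id, NULL))
  support <- lapply(seq_len(n_p), function(y) jj[ii == y][order(jj[ii == y])])

  structure(
    list(proteins = proteins, strings = strings, cond_FI = cond_FI,
         e_fo = e_fo, support = support, scheme = scheme, dud_rate = m,
         peptide_counts = peptide_counts),
    class = "proteome_model"
  )
}

as_protein_table <- function(proteins) {
  if (is.character(proteins)) {
    ids <- names(proteins)
    if (is.null(ids)) ids <- paste0("protein_", seq_along(proteins))
    proteins <- data.frame(id = ids, sequence = unname(proteins),
                           stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in%
                                           names(proteins)),
            nrow(proteins) >= 1L)
  proteins[c("id", "sequence")]
}

#' @export
print.proteome_model <- function(x, ...) {
  cat("Proteome model:", nrow(x$proteins), "proteins,",
      length(x$strings) - 1L, "observable fluorescence strings",
      "(+ f_null), dud rate", x$dud_rate, "\n")
  cat("  E_Fo range:", signif(min(x$e_fo), 4), "-", signif(max(x$e_fo), 4),
      "\n")
  invisible(x)
}

#' Number of fluorescence strings in a model's universe
#'
#' @param model a `proteome_model`.
#' @return `|D_F|`, counting the null string.
#' @export
n_strings <- function(model) length(model$strings)

#' Abundance vectors on the protein or indicator simplex
#'
#' Light wrapper tagging a probability vector with the space it lives in:
#' `"protein"` for relative molecular abundances p, `"indicator"` for the
#' per-read protein-indicator distribution q.
#'
#' @param values non-negative numeric vector summing to 1 (tolerance 1e-9).
#' @param space `"protein"` or `"indicator"`.
#' @return Numeric vector of class `abundance_vector` with a `space`
#'   attribute.
#' @export
abundance_vector <- function(values, space = c("protein", "indicator")) {
  space <- match.arg(space)
  values <- as.numeric(values)
  if (any(values < 0) || abs(sum(values) - 1) > 1e-9)
    stop("abundance vector must be a probability vector", call. = FALSE)
  structure(values, space = space, class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat("<abundance vector,", attr(x, "space"), "space, length", length(x),
      ">\n")
  print(as.numeric(x), ...)
  invisible(x)
}

e_fo_of <- function(model) {
  if (inherits(model, "proteome_model")) model$e_fo else as.numeric(model)
}

#' Protein abundances to indicator probabilities
#'
#' A protein's chance of generating a read is proportional to its abundance
#' times the expected number of observable fluorescence strings it sheds per
#' molecule: `q_y = E_Fo(y) p_y / sum_l E_Fo(l) p_l`.
#'
#' @param p protein-space probability vector.
#' @param model a `proteome_model`, or directly the numeric `E_Fo` vector.
#' @return Indicator-space `abundance_vector` q.
#' @examples
#' protein_to_indicator(c(0.5, 0.5), c(7.5, 2.5))  # -> 0.75 0.25
#' @export
protein_to_indicator <- function(p, model) {
  e <- e_fo_of(model)
  p <- as.numeric(p)
  stopifnot(length(p) == length(e))
  s <- sum(e * p)
  if (s == 0)
    stop("degenerate input: all abundance mass on unobservable proteins",
         call. = FALSE)
  abundance_vector(e * p / s, "indicator")
}

#' Indicator probabilities back to protein abundances
#'
#' Inverts [protein_to_indicator()]: `p_y` is proportional to
#' `q_y / E_Fo(y)`. Proteins that shed no observable string (`E_Fo = 0`)
#' must carry zero indicator mass.
#'
#' @param q indicator-space probability vector.
#' @param model a `proteome_model` or the numeric `E_Fo` vector.
#' @return Protein-space `abundance_vector` p.
#' @export
indicator_to_protein <- function(q, model) {
  e <- e_fo_of(model)
  q <- as.numeric(q)
  stopifnot(length(q) == length(e))
  if (any(q > 0 & e == 0))
    stop("inconsistent input: indicator mass on a protein with E_Fo = 0",
         call. = FALSE)
  p <- numeric(length(q))
  ok <- e > 0
  p[ok] <- q[ok] / e[ok]
  abundance_vector(p / sum(p), "protein")
}

#' Marginal fluorescence-string distribution
#'
#' Mixes the per-protein conditional string distributions with the indicator
#' probabilities: `P_Fo(f) = sum_y P(f | y) q_y`. This is the distribution
#' the read simulator draws generating strings from.
#'
#' @param q indicator-space probability vector.
#' @param model a `proteome_model`.
#' @return Numeric probability vector over the string universe (entry 1,
#'   the null string, is always 0).
#' @export
string_distribution <- function(q, model) {
  q <- as.numeric(q)
  stopifnot(length(q) == nrow(model$cond_FI))
  as.numeric(Matrix::crossprod(model$cond_FI, q))
}
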