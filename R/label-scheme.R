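#' Fluorophore labeling scheme
#'
#' Describes how peptides are chemically labeled: which protease generated
#' them and which amino acids each dye color targets. The default scheme uses
#' trypsin and three dye channels targeting aspartate/glutamate, cysteine and
#' tyrosine, the convention used by the published fluorosequencing peptide
#' classifiers.
#'
#' @param channels list of character vectors, one per dye color, each giving
#'   the single-letter amino acids targeted by that fluorophore. The sets must
#'   be pairwise disjoint.
#' @param protease name of the cleavage rule; `"trypsin"` is the only
#'   built-in rule (cleave C-terminal to K or R unless followed by P, zero
#'   missed cleavages).
#' @return An object of class `label_scheme` with elements `channels`,
#'   `n_channels` and `protease`.
#' @examples
#' sc <- label_scheme()
#' sc$n_channels
#' @export
label_scheme <- function(channels = list(c("D", "E"), "C", "Y"),
                         protease = "trypsin") {
  stopifnot(is.list(channels), length(channels) >= 1L)
  channels <- lapply(channels, function(x) {
    x <- as.character(x)
    if (!all(x %in% AA_STANDARD) || length(x) == 0L)
      stop("channel targets must be standard amino acids", call. = FALSE)
    sort(unique(x))
  })
  all_targets <- unlist(channels)
  if (anyDuplicated(all_targets))
    stop("channel amino-acid sets must be pairwise disjoint", call. = FALSE)
  if (!identical(protease, "trypsin"))
    stop("unknown protease: ", protease, " (only \"trypsin\" is built in)",
         call. = FALSE)
  structure(
    list(channels = channels, n_channels = length(channels),
         protease = protease),
    class = "label_scheme"
  )
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("Labeling scheme:", x$n_channels, "channels,", x$protease, "digestion\n")
  for (i in seq_along(x$channels))
    cat("  channel", i, "->", paste(x$channels[[i]], collapse = ","), "\n")
  invisible(x)
}

# The 20 standard residues accepted in protein sequences.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
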