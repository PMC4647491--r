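#' @include AllGenerics.R
NULL

#' Built-in structure-energy backend (base-pair maximization)
#'
#' A Nussinov-style dynamic programme that minimizes a pairwise
#' pseudo-energy with pair scores GC = -3, AU = -2, GU = -1 and a minimum
#' hairpin loop of 3 unpaired bases. The value is a pseudo-energy in model
#' units, not a thermodynamic free energy, but it preserves the ordering
#' the classifier relies on: sequences with more/stronger pairing score
#' lower (more negative).
#'
#' @return a [FoldingBackend].
#' @examples
#' foldSequence(builtinFoldingBackend(), "GGGAAACCC")
#' @export
builtinFoldingBackend <- function() {
    methods::new("FoldingBackend", name = "builtin",
                 fold = function(sequence) {
                     nussinov_energy(normalizeSeq(sequence), min_loop = 3L)
                 })
}

#' ViennaRNA RNAfold adapter backend
#'
#' Shells out to the `RNAfold` command-line folder and parses the minimum
#' free energy (kcal/mol) from its output. Requires the executable on the
#' PATH; see [hasRnafold()].
#'
#' @param cmd name or path of the RNAfold executable.
#' @return a [FoldingBackend].
#' @export
rnafoldBackend <- function(cmd = "RNAfold") {
    if (!nzchar(Sys.which(cmd)))
        stop("RNAfold executable not found: ", cmd)
    methods::new("FoldingBackend", name = "rnafold",
                 fold = function(sequence) {
                     out <- system2(cmd, args = c("--noPS"),
                                    input = normalizeSeq(sequence),
                                    stdout = TRUE, stderr = FALSE)
                     m <- regmatches(out, regexpr("\\(\\s*-?[0-9.]+\\s*\\)$",
                                                  out))
                     if (!length(m)) stop("could not parse RNAfold output")
                     min(0, as.numeric(gsub("[()\\s]", "",
                                            m[length(m)], perl = TRUE)))
                 })
}

#' Is the RNAfold executable available?
#' @param cmd executable name or path.
#' @return logical scalar.
#' @export
hasRnafold <- function(cmd = "RNAfold") nzchar(Sys.which(cmd))

#' Select a folding backend by configuration key
#'
#' @param backend `"builtin"` for the base-pair-maximization pseudo-energy,
#'   `"external"` for the RNAfold adapter, or a ready [FoldingBackend].
#' @return a [FoldingBackend].
#' @export
getFoldingBackend <- function(backend = c("builtin", "external")) {
    if (methods::is(backend, "FoldingBackend")) return(backend)
    backend <- match.arg(backend)
    if (backend == "builtin") builtinFoldingBackend() else rnafoldBackend()
}

setMethod("foldSequence", "FoldingBackend", function(backend, sequence) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (!nzchar(sequence)) stop("cannot fold an empty sequence")
    backend@fold(sequence)
})

#' Compute the structure energy of one transcript
#'
#' @param sequence nucleotide string (non-empty).
#' @param backend a [FoldingBackend] or configuration key for
#'   [getFoldingBackend()].
#' @param id transcript id used in error messages.
#' @return scalar energy in the backend's model units.
#' @export
computeMfe <- function(sequence, backend = builtinFoldingBackend(),
                       id = "") {
    backend <- getFoldingBackend(backend)
    tryCatch(foldSequence(backend, sequence),
             error = function(e) stop("folding backend '", backend@name,
                                      "' failed", if (nzchar(id))
                                          paste0(" on transcript ", id),
                                      ": ", conditionMessage(e),
                                      call. = FALSE))
}
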