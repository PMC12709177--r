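#' Define an RNA substrate
#'
#' A 5'->3' RNA sequence, optionally 5'-radiolabeled, with a set of
#' non-cleavable (phosphorothioate) internucleotide linkages: linkage `i`
#' joins residues `i` and `i + 1`.
#'
#' @param sequence RNA over `A`, `C`, `G`, `U` (upper-cased on input).
#' @param label `"five_prime_32P"` or `"none"`.
#' @param blocked_linkages Integer vector of 1-based linkage indices.
#' @return An `rna_substrate` object.
#' @export
rna_substrate <- function(sequence, label = c("five_prime_32P", "none"),
                          blocked_linkages = integer(0)) {
  label <- match.arg(label)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  abort_if(length(chars) < 1L, "empty RNA sequence",
           class = "nrnbkit_validation_error")
  bad <- setdiff(unique(chars), c("A", "C", "G", "U"))
  abort_if(length(bad) > 0, "invalid RNA character(s): ",
           paste(bad, collapse = ", "),
           class = "nrnbkit_validation_error")
  blocked_linkages <- as.integer(blocked_linkages)
  if (length(blocked_linkages)) {
    abort_if(length(chars) < 2L, "a substrate with linkages needs length >= 2",
             class = "nrnbkit_validation_error")
    abort_if(any(blocked_linkages < 1L) ||
               any(blocked_linkages > length(chars) - 1L),
             "blocked linkage index out of range",
             class = "nrnbkit_validation_error")
  }
  structure(list(sequence = sequence, label = label,
                 blocked_linkages = sort(unique(blocked_linkages))),
            class = "rna_substrate")
}

#' Simulate a processive exonuclease degradation ladder
#'
#' Residues are removed one at a time from the 3' end (`three_to_five`) or
#' the 5' end (`five_to_three`). A cleavage step is forbidden when it would
#' sever a blocked linkage, so degradation stalls there: with 3'-5' polarity
#' and a block at linkage `i` the stall product is the 5' prefix of length
#' `i + 1`; with 5'-3' polarity it is the 3' suffix starting at residue `i`
#' (and the first removed species carries the 5' label). Without blocks the
#' substrate is fully processed to mononucleotides.
#'
#' @param substrate An [rna_substrate()].
#' @param polarity `"three_to_five"` or `"five_to_three"`.
#' @return A `degradation_ladder`: `polarity`, `labeled_species` (lengths
#'   of 5'-labeled species after each cleavage step), `final_products`
#'   (sequences), `stall_product` (sequence or `NA` when degradation runs
#'   to completion).
#' @export
simulate_exo_ladder <- function(substrate,
                                polarity = c("three_to_five",
                                             "five_to_three")) {
  polarity <- match.arg(polarity)
  seq <- substrate$sequence
  L <- nchar(seq)
  blocks <- substrate$blocked_linkages
  if (L == 1L) {
    return(structure(list(polarity = polarity, labeled_species = integer(0),
                          final_products = seq, stall_product = NA_character_),
                     class = "degradation_ladder"))
  }
  removed <- character(0)
  labeled <- integer(0)
  if (polarity == "three_to_five") {
    # removing the 3'-terminal residue of a fragment of length l severs
    # linkage l-1; the first block met from the 3' end is the largest index
    stall_len <- if (length(blocks)) max(blocks) + 1L else 1L
    cur <- L
    while (cur > stall_len) {
      removed <- c(removed, substring(seq, cur, cur))
      cur <- cur - 1L
      labeled <- c(labeled, cur)   # the 5'-labeled fragment shrinks
    }
    remainder <- substring(seq, 1L, cur)
    stall <- if (length(blocks)) remainder else NA_character_
    products <- c(remainder, removed)
  } else {
    # removing the 5'-terminal residue (original index r) severs linkage r
    stall_start <- if (length(blocks)) min(blocks) else L
    r <- 1L
    while (r < stall_start) {
      removed <- c(removed, substring(seq, r, r))
      if (r == 1L && substrate$label == "five_prime_32P") {
        labeled <- c(labeled, 1L)  # the label leaves on the 5' mononucleotide
      }
      r <- r + 1L
    }
    remainder <- substring(seq, r, L)
    stall <- if (length(blocks)) remainder else NA_character_
    products <- c(removed, remainder)
  }
  structure(list(polarity = polarity, labeled_species = labeled,
                 final_products = products, stall_product = stall),
            class = "degradation_ladder")
}

#' Infer exonuclease polarity from a substrate/intermediate pair
#'
#' A proper 5'-anchored prefix implies 3'-5' processing; a proper
#' 3'-anchored suffix implies 5'-3'; identity means no processing; a
#' fragment that is both prefix and suffix (repeated termini) is ambiguous;
#' anything else is inconsistent with simple exonucleolytic trimming.
#'
#' @param substrate,intermediate RNA sequences (strings or
#'   [rna_substrate()] objects).
#' @return List with `call` (one of `three_to_five`, `five_to_three`,
#'   `no_processing`, `ambiguous`, `inconsistent`) and `residues_removed`.
#' @export
infer_polarity <- function(substrate, intermediate) {
  s <- if (inherits(substrate, "rna_substrate")) substrate$sequence
       else toupper(substrate)
  x <- if (inherits(intermediate, "rna_substrate")) intermediate$sequence
       else toupper(intermediate)
  abort_if(nchar(s) == 0L || nchar(x) == 0L, "sequences must be non-empty",
           class = "nrnbkit_validation_error")
  abort_if(nchar(x) > nchar(s),
           "intermediate is longer than the substrate",
           class = "nrnbkit_validation_error")
  removed <- nchar(s) - nchar(x)
  if (removed == 0L) {
    call <- if (identical(s, x)) "no_processing" else "inconsistent"
    return(list(call = call, residues_removed = 0L))
  }
  is_prefix <- substring(s, 1L, nchar(x)) == x
  is_suffix <- substring(s, removed + 1L, nchar(s)) == x
  call <- if (is_prefix && is_suffix) "ambiguous"
          else if (is_prefix) "three_to_five"
          else if (is_suffix) "five_to_three"
          else "inconsistent"
  list(call = call, residues_removed = removed)
}

#' Normalize a substrate-depletion trace to its first time point
#'
#' @param time_min Numeric time points (minutes), in acquisition order.
#' @param intensity Non-negative band intensities (arbitrary units); the
#'   first intensity must be positive.
#' @return A `depletion_trace` data.frame: `time_min`, `intensity`,
#'   `normalized` (first point = 1.0).
#' @export
normalize_depletion <- function(time_min, intensity) {
  abort_if(length(intensity) < 1L || length(time_min) != length(intensity),
           "time and intensity must be equal-length, non-empty",
           class = "nrnbkit_validation_error")
  abort_if(any(intensity < 0), "intensities must be >= 0",
           class = "nrnbkit_validation_error")
  abort_if(intensity[1] <= 0, "first time point intensity must be > 0",
           class = "nrnbkit_validation_error")
  structure(data.frame(time_min = time_min, intensity = intensity,
                       normalized = intensity / intensity[1]),
            class = c("depletion_trace", "data.frame"))
}

#' Fit a phosphate standard curve
#'
#' Ordinary least squares of absorbance on concentration:
#' `absorbance = slope * concentration + intercept`.
#'
#' @param conc_uM Concentrations (at least 2 distinct values).
#' @param absorbance Matching absorbance readings.
#' @return A `standard_curve`: `slope`, `intercept`, `residual_sd`,
#'   `range` (calibrated concentration range).
#' @export
fit_standard_curve <- function(conc_uM, absorbance) {
  abort_if(length(conc_uM) < 2L || length(conc_uM) != length(absorbance),
           "need >= 2 (concentration, absorbance) points",
           class = "nrnbkit_validation_error")
  abort_if(length(unique(conc_uM)) < 2L,
           "all concentrations identical; cannot fit a line",
           class = "nrnbkit_fit_error")
  fit <- lm(absorbance ~ conc_uM)
  res <- fit$residuals
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 residual_sd = if (length(res) > 2)
                   sqrt(sum(res^2) / (length(res) - 2)) else 0,
                 range = range(conc_uM)),
            class = "standard_curve")
}

#' Invert a standard curve: absorbance to concentration
#'
#' @param curve A [fit_standard_curve()] result.
#' @param absorbance Absorbance reading(s).
#' @return List with `conc_uM` and `extrapolated` (logical; `TRUE` when the
#'   solved concentration lies outside the calibrated range).
#' @export
invert_standard_curve <- function(curve, absorbance) {
  abort_if(curve$slope == 0, "zero slope; curve not invertible",
           class = "nrnbkit_fit_error")
  conc <- (absorbance - curve$intercept) / curve$slope
  list(conc_uM = conc,
       extrapolated = conc < curve$range[1] | conc > curve$range[2])
}

#' Stoichiometric upper bound on phosphate release from c-di-AMP
#'
#' In the coupled alkaline-phosphatase assay, intact c-di-AMP exposes no
#' phosphatase-accessible phosphate; linearization to pApA exposes one 5'
#' phosphate per molecule; complete processing to AMP yields two.
#'
#' @param c_di_amp_conc Concentration in uM (>= 0).
#' @param processing One of `"none"`, `"linearized"`, `"to_AMP"`.
#' @return Released phosphate upper bound in uM.
#' @export
cdiamp_expected_phosphate <- function(c_di_amp_conc,
                                      processing = c("none", "linearized",
                                                     "to_AMP")) {
  processing <- match.arg(processing)
  abort_if(any(c_di_amp_conc < 0), "concentration must be >= 0",
           class = "nrnbkit_validation_error")
  mult <- switch(processing, none = 0, linearized = 1, to_AMP = 2)
  c_di_amp_conc * mult
}

#' Read a depletion trace TSV (columns time_min, intensity)
#' @param path TSV path.
#' @return A normalized `depletion_trace`.
#' @export
read_depletion_tsv <- function(path) {
  df <- read_tsv(path)
  abort_if(!all(c("time_min", "intensity") %in% names(df)),
           "trace TSV needs columns time_min, intensity",
           class = "nrnbkit_parse_error")
  normalize_depletion(df$time_min, df$intensity)
}

#' Read a standard-curve TSV (columns conc_uM, a620) and fit it
#' @param path TSV path.
#' @return A `standard_curve`.
#' @export
read_standard_curve_tsv <- function(path) {
  df <- read_tsv(path)
  abort_if(!all(c("conc_uM", "a620") %in% names(df)),
           "standard-curve TSV needs columns conc_uM, a620",
           class = "nrnbkit_parse_error")
  fit_standard_curve(df$conc_uM, df$a620)
}
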