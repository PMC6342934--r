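#' Parameterized PAM activity model for a simulated nuclease
#'
#' Ground-truth generative model for depletion screens: each PAM position
#' carries a per-base activity factor in `[0, 1]` and the activity of a PAM
#' is the product over positions. A plasmid carrying a PAM with activity `a`
#' is eliminated from the selected library with probability
#' `depletion_strength * a`.
#'
#' Positions are ordered 5' to 3', i.e. column 1 of the PAM string is the
#' most distal position (-k) and the last column (-1) abuts the protospacer.
#'
#' @param weights numeric matrix of per-position, per-base activity factors
#'   in `[0, 1]`; rows are positions (distal to proximal), columns are bases
#'   A, C, G, T. A matrix of all ones is active at every PAM.
#' @param depletion_strength probability in `[0, 1]` that a plasmid with
#'   activity 1 is eliminated.
#' @return an object of class `nuclease_pam_model`.
#' @seealso [pam_model_from_iupac()] for 0/1 models written as a motif,
#'   [pam_activity()] to evaluate the model.
#' @export
#' @examples
#' m <- pam_model_from_iupac("NNNNTTTN")
#' pam_activity(m, c("GCGCTTTA", "GCGCATTA"))
nuclease_pam_model <- function(weights, depletion_strength = 0.95) {
  weights <- as.matrix(weights)
  if (ncol(weights) != 4L) {
    stop("'weights' must have 4 columns (bases A, C, G, T)", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0) || any(weights > 1)) {
    stop("all weights must be finite and in [0, 1]", call. = FALSE)
  }
  assert_prob(depletion_strength)
  colnames(weights) <- DNA_BASES
  rownames(weights) <- paste0("pos", -nrow(weights):-1)
  structure(list(weights = weights, depletion_strength = depletion_strength),
            class = "nuclease_pam_model")
}

#' Build a 0/1 PAM model from an IUPAC motif
#'
#' Bases covered by the code at each position get weight 1, all others 0;
#' the model's activity is 1 exactly on PAMs matching the motif.
#'
#' @param iupac IUPAC string, one code per PAM position (5' to 3').
#' @inheritParams nuclease_pam_model
#' @return an object of class `nuclease_pam_model`.
#' @export
pam_model_from_iupac <- function(iupac, depletion_strength = 0.95) {
  codes <- strsplit(toupper(iupac), "")[[1]]
  if (length(codes) == 0L || !all(codes %in% names(IUPAC_SETS))) {
    stop("'iupac' must be a non-empty string of IUPAC nucleotide codes",
         call. = FALSE)
  }
  w <- t(vapply(codes, function(cd) as.numeric(DNA_BASES %in% IUPAC_SETS[[cd]]),
                numeric(4)))
  nuclease_pam_model(w, depletion_strength)
}

#' Evaluate PAM activity under a model
#'
#' @param model a [nuclease_pam_model()].
#' @param pams character vector of PAMs over A/C/G/T, each of length
#'   `nrow(model$weights)`.
#' @return numeric vector of activities in `[0, 1]`.
#' @export
pam_activity <- function(model, pams) {
  stopifnot(inherits(model, "nuclease_pam_model"))
  k <- nrow(model$weights)
  if (any(nchar(pams) != k)) {
    stop(sprintf("all PAMs must have length %d", k), call. = FALSE)
  }
  if (length(pams) == 0L) return(numeric(0))
  base_idx <- matrix(match(strsplit(paste(pams, collapse = ""), "")[[1]],
                           DNA_BASES),
                     nrow = k)
  if (anyNA(base_idx)) stop("PAMs must be over A/C/G/T", call. = FALSE)
  w <- model$weights
  act <- rep(1, length(pams))
  for (p in seq_len(k)) act <- act * w[p, base_idx[p, ]]
  unname(act)
}

#' @export
print.nuclease_pam_model <- function(x, ...) {
  cat(sprintf("nuclease_pam_model: %d PAM positions, depletion_strength %.3g\n",
              nrow(x$weights), x$depletion_strength))
  print(round(x$weights, 3))
  invisible(x)
}
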