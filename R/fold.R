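#' Fold an RNA/DNA sequence with a stacking-energy model
#'
#' Computes the minimum-energy non-crossing secondary structure under a
#' simplified nearest-neighbour model: G:C, A:U and G:U pairs are allowed,
#' unpaired bases and isolated pairs contribute 0, and each stack of two
#' adjacent pairs contributes -3.0 kcal/mol when both pairs are G:C,
#' -2.0 when the weakest pair in the stack is A:U, and -1.0 when it is G:U.
#' Hairpin loops must contain at least `min_loop` unpaired bases and
#' pseudoknots are excluded. This is a deliberately fully-specified stand-in
#' for heavyweight thermodynamic folders; energy thresholds used elsewhere in
#' the package are interpreted on this model's scale.
#'
#' @param sequence a single RNA or DNA string (U and T are equivalent).
#' @param min_loop minimum hairpin loop size in nt (default 3).
#' @return list with `structure` (dot-bracket string) and `energy`
#'   (kcal/mol, `<= 0`).
#' @examples
#' fold_rna("GGGAAACCC") # three G:C pairs, two stacks, -6 kcal/mol
#' @export
fold_rna <- function(sequence, min_loop = 3L) {
  .stop_if(length(sequence) != 1L, "fold_rna() folds one sequence at a time")
  s <- normalize_dna(sequence)
  .stop_if(!.valid_dna(s, allow_n = FALSE),
           "sequence contains characters outside A/C/G/T/U")
  .stop_if(nchar(s) > 200L, "sequence longer than 200 nt")
  res <- fold_rna_cpp(s, as.integer(min_loop))
  list(structure = res$structure, energy = res$energy)
}

#' Minimum free energy of an intermolecular RNA:RNA duplex
#'
#' Hybridization energy between two sequences under the same stacking model
#' as [fold_rna()]: antiparallel, non-crossing base pairs (G:C, A:U, G:U),
#' isolated pairs free, adjacent pairs stacking at -3/-2/-1 kcal/mol.
#' Returns 0 when no pair can form. Symmetric in its arguments.
#'
#' @param a,b sequences (RNA or DNA).
#' @return duplex energy in kcal/mol, `<= 0`.
#' @export
duplex_free_energy <- function(a, b) {
  .stop_if(length(a) != 1L || length(b) != 1L, "a and b must be single strings")
  a <- normalize_dna(a); b <- normalize_dna(b)
  .stop_if(!.valid_dna(a, FALSE) || !.valid_dna(b, FALSE),
           "sequences contain characters outside A/C/G/T/U")
  .stop_if(nchar(a) > 40L || nchar(b) > 40L, "duplex sequences must be <= 40 nt")
  duplex_energy_cpp(a, b)
}

# pair table (partner index per position, NA if unpaired) from dot-bracket
.pair_table <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  n <- length(ch)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  partner
}
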