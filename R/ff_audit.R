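# Force-field audit for conjugated chains: bond lengths along a chain,
# bond-length alternation (BLA), and comparison of parameter sets against a
# quantum-mechanical reference.

#' Bond lengths along a chain of atoms
#'
#' Euclidean distances between consecutive atoms of a chain.
#'
#' @param geometry natoms x 3 matrix, Angstrom.
#' @param chain integer vector of atom indices (1-based), length >= 2,
#'   no repeats.
#' @return numeric vector of `length(chain) - 1` bond lengths, Angstrom.
#' @export
chain_bond_lengths <- function(geometry, chain) {
  geometry <- as.matrix(geometry)
  if (anyDuplicated(chain)) stop("repeated atom index in chain")
  if (length(chain) < 2) stop("chain needs at least 2 atoms")
  if (any(chain < 1) || any(chain > nrow(geometry))) stop("chain index out of range")
  d <- diff(geometry[chain, , drop = FALSE])
  sqrt(rowSums(d^2))
}

#' Bond-length alternation
#'
#' Default definition: mean absolute difference of consecutive bond lengths,
#' which is zero for a fully delocalized chain and grows with single/double
#' bond localization. `method = "odd_even"` instead returns the difference
#' between the mean odd-indexed and mean even-indexed bond lengths.
#' Both definitions are invariant under reversal of the chain direction.
#'
#' @param lengths bond lengths, Angstrom (>= 2 values).
#' @param method `"mean_abs_diff"` (default) or `"odd_even"`.
#' @return BLA in Angstrom.
#' @export
bond_length_alternation <- function(lengths, method = c("mean_abs_diff",
                                                        "odd_even")) {
  method <- match.arg(method)
  if (length(lengths) < 2) stop("need at least 2 bond lengths")
  if (any(lengths <= 0.5) || any(lengths >= 3.0)) {
    stop("bond lengths outside the plausible (0.5, 3.0) Angstrom range")
  }
  switch(method,
    mean_abs_diff = mean(abs(diff(lengths))),
    odd_even = {
      odd <- lengths[seq(1, length(lengths), by = 2)]
      even <- lengths[seq(2, length(lengths), by = 2)]
      abs(mean(odd) - mean(even))
    }
  )
}

#' Compare bond-parameter sets against a reference
#'
#' Per-bond signed deviations (`test - reference`), summary statistics, BLA
#' ratio and a pass/flag verdict at a configurable deviation threshold.
#'
#' @param table data.frame of bond lengths (Angstrom) with one row per bond
#'   (row names label the bonds) and one column per source.
#' @param reference,test column names.
#' @param threshold flag threshold on the absolute deviation, Angstrom.
#' @return list: `deviations` (signed, named), `max_deviation`,
#'   `max_deviation_bond`, `bla_reference`, `bla_test`, `bla_ratio`, `pass`.
#' @export
compare_parameter_sets <- function(table, reference, test, threshold = 0.02) {
  if (!all(c(reference, test) %in% names(table))) {
    stop("reference/test column not present in the table")
  }
  dev <- table[[test]] - table[[reference]]
  names(dev) <- rownames(table)
  imax <- which.max(abs(dev))
  bla_ref <- bond_length_alternation(table[[reference]])
  bla_test <- bond_length_alternation(table[[test]])
  list(
    deviations = dev,
    max_deviation = abs(dev[imax]),
    max_deviation_bond = rownames(table)[imax],
    bla_reference = bla_ref,
    bla_test = bla_test,
    bla_ratio = bla_test / bla_ref,
    pass = max(abs(dev)) <= threshold
  )
}

#' Packaged polymethine bond-length table
#'
#' Equilibrium bond lengths (Angstrom) of a trimethine cyanine's conjugated
#' chain from wB97XD/Def2SVP-optimized ground (S0) and first excited (S1)
#' states, alongside the Amber99SB-dyes force-field equilibrium values and
#' force constants (kJ mol^-1 nm^-2). Rows run from one ring nitrogen to the
#' other; the four central rows are the polymethine C-C bonds.
#'
#' @param cc_only return only the four C-C chain bonds (drop the terminal
#'   N-C rows); this is the subset on which BLA is chemically meaningful.
#' @return data.frame with columns `R0_QM_S0`, `R0_QM_S1`, `R0_FF`, `k_FF`
#'   and bond-label row names.
#' @export
cy3_bond_table <- function(cc_only = FALSE) {
  path <- system.file("extdata", "cy3_polymethine_bonds.csv",
                      package = "vibronic")
  dat <- utils::read.csv(path, comment.char = "#", row.names = 1)
  if (cc_only) dat <- dat[c("R(1,2)", "R(2,3)", "R(3,4)", "R(4,5)"), ]
  dat
}
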