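#' Distance bounds from NOE intensity classes
#'
#' Maps the qualitative cross-peak classes used in restraint derivation
#' to lower/upper distance bounds: strong and weak cross-peaks in the
#' short-mixing-time NOESY give 2--4 and 4--6 \AA{}, cross-peaks seen
#' only at long mixing time 4--8 \AA{}, amide-amide cross-peaks
#' 2--6 \AA{}, intermethyl peaks from a single (long-mixing) dataset
#' 2--8 \AA{}, and hydrogen-bond donor restraints 0--2 \AA{} (H donor)
#' or 0--3 \AA{} (N donor).
#'
#' @param peak_class One of \code{"strong_short_mix"},
#'   \code{"weak_short_mix"}, \code{"long_mix_only"}, \code{"hn_hn"},
#'   \code{"single_dataset_2_8"}, \code{"hbond_donor_H"},
#'   \code{"hbond_donor_N"}.
#' @return Numeric \code{c(lower, upper)} in \AA{}.
#' @examples
#' derive_bounds("strong_short_mix")  # 2 4
#' @export
derive_bounds <- function(peak_class) {
  tab <- list(strong_short_mix = c(2, 4), weak_short_mix = c(4, 6),
              long_mix_only = c(4, 8), hn_hn = c(2, 6),
              single_dataset_2_8 = c(2, 8), hbond_donor_H = c(0, 2),
              hbond_donor_N = c(0, 3))
  if (length(peak_class) != 1L || !peak_class %in% names(tab))
    .stopf("unknown peak class '%s'", paste(peak_class, collapse = ","))
  setNames(tab[[peak_class]], c("lower", "upper"))
}

#' Build a distance-restraint table
#'
#' A restraint connects two atom groups, each either a single atom
#' (e.g. an amide H) or a methyl proton triplet represented by its
#' barycenter pseudo-atom.  Bounds may be given explicitly or derived
#' from a peak class via [derive_bounds()].
#'
#' @param resid_i,resid_j Residue numbers of the two groups.
#' @param atoms_i,atoms_j Atom names of each group: a single name, or
#'   three semicolon-joined proton names for a methyl barycenter
#'   (e.g. \code{"HD11;HD12;HD13"}).
#' @param peak_class Optional per-restraint class, see
#'   [derive_bounds()].
#' @param lower,upper Explicit bounds in \AA{} (override the class).
#' @param id Restraint identifiers; autogenerated when missing.
#' @param state_tag \code{"unassigned"}, \code{"open_specific"},
#'   \code{"closed_specific"} or \code{"shared"}.
#' @return A data frame of class \code{"restraint_table"} with columns
#'   \code{id, resid_i, atoms_i, resid_j, atoms_j, lower, upper, class,
#'   state_tag}.
#' @export
restraint_table <- function(resid_i, atoms_i, resid_j, atoms_j,
                            peak_class = NULL, lower = NULL, upper = NULL,
                            id = NULL, state_tag = "unassigned") {
  n <- length(resid_i)
  if (!is.null(peak_class)) {
    b <- vapply(rep_len(peak_class, n), derive_bounds, numeric(2))
    if (is.null(lower)) lower <- b[1, ]
    if (is.null(upper)) upper <- b[2, ]
  }
  if (is.null(lower) || is.null(upper))
    .stopf("either peak_class or explicit lower/upper bounds are required")
  if (is.null(id)) id <- sprintf("r%03d", seq_len(n))
  out <- data.frame(id = id, resid_i = as.integer(resid_i),
                    atoms_i = atoms_i, resid_j = as.integer(resid_j),
                    atoms_j = atoms_j, lower = rep_len(lower, n),
                    upper = rep_len(upper, n),
                    class = if (is.null(peak_class)) "explicit"
                            else rep_len(peak_class, n),
                    state_tag = rep_len(state_tag, n))
  .validate_restraints(out)
}

.validate_restraints <- function(df) {
  req <- c("id", "resid_i", "atoms_i", "resid_j", "atoms_j",
           "lower", "upper", "class", "state_tag")
  miss <- setdiff(req, names(df))
  if (length(miss)) .stopf("restraint table missing column(s): %s",
                           paste(miss, collapse = ", "))
  df$resid_i <- as.integer(df$resid_i)
  df$resid_j <- as.integer(df$resid_j)
  df$lower <- as.numeric(df$lower)
  df$upper <- as.numeric(df$upper)
  # hydrogen-bond classes legitimately have lower = 0; all others must
  # have a positive lower bound below the upper bound
  bad <- df$lower < 0 | df$upper <= df$lower |
    (df$lower == 0 & !grepl("^hbond", df$class))
  if (any(bad)) .stopf("invalid bounds for restraint(s) %s",
                       paste(df$id[bad], collapse = ", "))
  ng <- function(a) lengths(strsplit(a, ";", fixed = TRUE))
  if (!all(ng(df$atoms_i) %in% c(1L, 3L)) || !all(ng(df$atoms_j) %in% c(1L, 3L)))
    .stopf("atom groups must list 1 atom or 3 protons (semicolon-joined)")
  class(df) <- c("restraint_table", "data.frame")
  df
}

#' Position of an atom group in a model
#'
#' Single-atom groups resolve to the atom's coordinates; three-proton
#' groups resolve to the unweighted barycenter of the protons.
#'
#' @param model \eqn{N \times 3} coordinate matrix.
#' @param atoms Atom table (see [conformer_ensemble()]).
#' @param resid Residue number.
#' @param atom_names Character vector of 1 or 3 atom names.
#' @return Numeric length-3 position.
#' @export
group_position <- function(model, atoms, resid, atom_names) {
  if (!length(atom_names) %in% c(1L, 3L))
    .stopf("an atom group lists 1 atom or exactly 3 protons")
  idx <- vapply(atom_names, function(a) {
    i <- which(atoms$resno == resid & atoms$name == a)
    if (!length(i))
      .stopf("atom %s of residue %d not found in the model", a, resid)
    i[1]
  }, integer(1))
  if (length(idx) == 1L) model[idx, ] else colMeans(model[idx, , drop = FALSE])
}

.group_atoms <- function(spec) strsplit(spec, ";", fixed = TRUE)[[1]]

#' Distance between the two groups of a restraint
#'
#' Euclidean distance between the group positions (barycenter geometry
#' for methyl triplets).  With \code{averaging = "r6"} the
#' \eqn{\langle r^{-6}\rangle^{-1/6}} average over all proton pairs is
#' returned instead, for sensitivity analysis.
#'
#' @param model Coordinate matrix.
#' @param atoms Atom table.
#' @param restraint One row of a [restraint_table()].
#' @param averaging \code{"barycenter"} (default) or \code{"r6"}.
#' @return Distance in \AA{}.
#' @export
restraint_distance <- function(model, atoms, restraint,
                               averaging = c("barycenter", "r6")) {
  averaging <- match.arg(averaging)
  ai <- .group_atoms(restraint$atoms_i)
  aj <- .group_atoms(restraint$atoms_j)
  if (averaging == "barycenter") {
    pi_ <- group_position(model, atoms, restraint$resid_i, ai)
    pj <- group_position(model, atoms, restraint$resid_j, aj)
    return(sqrt(sum((pi_ - pj)^2)))
  }
  xi <- t(vapply(ai, function(a) group_position(model, atoms, restraint$resid_i, a),
                 numeric(3)))
  xj <- t(vapply(aj, function(a) group_position(model, atoms, restraint$resid_j, a),
                 numeric(3)))
  d6 <- outer(seq_len(nrow(xi)), seq_len(nrow(xj)),
              Vectorize(function(u, v) sum((xi[u, ] - xj[v, ])^2)^(-3)))
  mean(d6)^(-1 / 6)
}

#' Restraint satisfaction on an ensemble
#'
#' Evaluates every restraint on every model.  A restraint is satisfied
#' by a model when its distance is at most \code{upper + tolerance}
#' (lower bounds are reported but by default do not affect the verdict,
#' matching the upper-bound notion of an NOE violation; set
#' \code{use_lower = TRUE} to include them).  Ensemble-level
#' satisfaction is judged either on the representative (medoid) model
#' (default) or by requiring a fraction of members.
#'
#' @param ens A [conformer_ensemble()].
#' @param restraints A [restraint_table()].
#' @param tolerance Slack above the upper bound, \AA{}.
#' @param mode \code{"representative"} or \code{"fraction"}.
#' @param fraction Required fraction of satisfying members when
#'   \code{mode = "fraction"}.
#' @param use_lower Also require \code{distance >= lower - tolerance}.
#' @param averaging Distance definition, see [restraint_distance()].
#' @return An object of class \code{"restraint_evaluation"}: per-model
#'   records (\code{restraint_id}, \code{model}, \code{distance},
#'   \code{satisfied}, \code{margin} = upper - distance) and the
#'   ensemble-level verdict per restraint.
#' @export
evaluate_on_ensemble <- function(ens, restraints, tolerance = 0.5,
                                 mode = c("representative", "fraction"),
                                 fraction = 0.5, use_lower = FALSE,
                                 averaging = "barycenter") {
  stopifnot(inherits(ens, "conformer_ensemble"))
  mode <- match.arg(mode)
  restraints <- .validate_restraints(as.data.frame(restraints))
  nm <- n_models(ens)
  rec <- vector("list", nrow(restraints))
  for (r in seq_len(nrow(restraints))) {
    d <- vapply(ens$models, function(m)
      restraint_distance(m, ens$atoms, restraints[r, ], averaging),
      numeric(1))
    sat <- d <= restraints$upper[r] + tolerance
    if (use_lower) sat <- sat & d >= restraints$lower[r] - tolerance
    rec[[r]] <- data.frame(restraint_id = restraints$id[r],
                           model = seq_len(nm), distance = d,
                           satisfied = sat,
                           margin = restraints$upper[r] - d)
  }
  records <- do.call(rbind, rec)
  rep_model <- if (mode == "representative") representative_model(ens) else NA_integer_
  verdict <- vapply(seq_len(nrow(restraints)), function(r) {
    sat <- rec[[r]]$satisfied
    if (mode == "representative") sat[rep_model] else mean(sat) >= fraction
  }, logical(1))
  structure(list(records = records,
                 by_restraint = data.frame(id = restraints$id,
                                           satisfied = verdict),
                 representative = rep_model, tolerance = tolerance,
                 mode = mode),
            class = "restraint_evaluation")
}

#' @export
print.restraint_evaluation <- function(x, ...) {
  n <- nrow(x$by_restraint)
  cat(sprintf("Restraint evaluation (%s mode, tolerance %g A): %d/%d satisfied\n",
              x$mode, x$tolerance, sum(x$by_restraint$satisfied), n))
  invisible(x)
}

#' Partition restraints between two conformational states
#'
#' Classifies each restraint by its satisfaction in two ensembles
#' sharing residue numbering: satisfied only in A, only in B, in both,
#' or in neither — the state-specificity analysis separating restraints
#' characteristic of each conformation from those shared by both.
#'
#' @param restraints A [restraint_table()].
#' @param ensemble_A,ensemble_B Two [conformer_ensemble()]s.
#' @param tolerance Slack above upper bounds, \AA{}.
#' @param ... Passed to [evaluate_on_ensemble()].
#' @return An object of class \code{"restraint_partition"}: per-restraint
#'   classification and the counts \code{A_only}, \code{B_only},
#'   \code{both}, \code{neither} (summing to the number of restraints).
#' @export
partition_two_states <- function(restraints, ensemble_A, ensemble_B,
                                 tolerance = 0.5, ...) {
  restraints <- .validate_restraints(as.data.frame(restraints))
  for (side in list(c("A"), c("B"))) {
    ens <- if (side == "A") ensemble_A else ensemble_B
    have <- unique(ens$atoms$resno)
    need <- unique(c(restraints$resid_i, restraints$resid_j))
    missing <- setdiff(need, have)
    if (length(missing))
      .stopf("residue(s) %s referenced by restraints are absent from ensemble %s",
             paste(missing, collapse = ", "), side)
  }
  ev_a <- evaluate_on_ensemble(ensemble_A, restraints, tolerance, ...)
  ev_b <- evaluate_on_ensemble(ensemble_B, restraints, tolerance, ...)
  sa <- ev_a$by_restraint$satisfied
  sb <- ev_b$by_restraint$satisfied
  cls <- ifelse(sa & sb, "both",
                ifelse(sa, "A_only", ifelse(sb, "B_only", "neither")))
  counts <- c(A_only = sum(cls == "A_only"), B_only = sum(cls == "B_only"),
              both = sum(cls == "both"), neither = sum(cls == "neither"))
  structure(list(table = data.frame(id = restraints$id, class = cls,
                                    satisfied_A = sa, satisfied_B = sb),
                 counts = counts, tolerance = tolerance,
                 eval_A = ev_a, eval_B = ev_b),
            class = "restraint_partition")
}

#' @export
print.restraint_partition <- function(x, ...) {
  cat(sprintf("Two-state restraint partition (tolerance %g A):\n", x$tolerance))
  cat(sprintf("  A only: %d   B only: %d   both: %d   neither: %d\n",
              x$counts[["A_only"]], x$counts[["B_only"]],
              x$counts[["both"]], x$counts[["neither"]]))
  invisible(x)
}
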