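# Synthetic-data generators.  These define the package's reference study
# conditions: a WT-like methyl multiple-quantum dataset (21 probes, two
# fields at 700 and 850 MHz, 16 CPMG frequencies between 66 and 2000 Hz
# in a 30 ms period, 2% multiplicative noise) around the fitted
# operating point p_excited = 0.032, k_ex = 2490 s^-1 at 293 K, and a
# two-conformation toy protein with a rigid core and a mobile segment
# carrying methyl pseudo-atoms.

#' WT-like methyl probe set
#'
#' A deterministic set of methyl multiple-quantum probes with shift
#' differences spread over the ranges typical of methyl-TROSY dispersion
#' work (|dw_C| 0.35--2.2 ppm, |dw_H| 0.02--0.25 ppm) and exchange-free
#' baselines of 8--25 s\eqn{^{-1}} growing with field.
#'
#' @param n_probes Number of probes.
#' @param fields_MHz Static fields.
#' @return List of [probe_params()].
#' @export
wt_methyl_probes <- function(n_probes = 21, fields_MHz = c(700, 850)) {
  res_types <- c("I", "L", "M", "T", "V", "A")
  methyls <- c("CD1", "CD2", "CE", "CG2", "CG1", "CB")
  dw_x <- seq(0.75, 2.2, length.out = n_probes)
  # interleave so neighbouring probes differ (fixed permutation)
  ord <- order(rep_len(seq_len(3), n_probes), seq_len(n_probes))
  dw_x <- dw_x[ord]
  dw_h <- seq(0.02, 0.25, length.out = n_probes)[rev(ord)]
  base <- seq(8, 22, length.out = n_probes)[ord]
  lapply(seq_len(n_probes), function(i) {
    k <- ((i - 1) %% length(res_types)) + 1
    probe_params(sprintf("%s%d-%s", res_types[k], 100 + i, methyls[k]),
                 "CH3_MQ", dw_X = dw_x[i], dw_H = dw_h[i],
                 r2_base = setNames(base[i] * (fields_MHz / 700)^0.5,
                                    format(fields_MHz)))
  })
}

#' Ground truth of a synthetic dispersion experiment
#'
#' @param exch [exchange_params()]; defaults to the WT-like operating
#'   point (p_excited = 0.032, k_ex = 2490 s\eqn{^{-1}}, 293 K).
#' @param probes List of [probe_params()]; defaults to
#'   [wt_methyl_probes()].
#' @param fields_MHz Static fields.
#' @param noise_fraction Gaussian noise std as a fraction of
#'   \eqn{R_{2,eff}} (default 0.02).
#' @param seed RNG seed recorded with every generated artefact.
#' @return An object of class \code{"synthetic_truth"}.
#' @export
synthetic_truth <- function(exch = exchange_params(0.032, 2490, 293),
                            probes = NULL, fields_MHz = c(700, 850),
                            noise_fraction = 0.02, seed = 1) {
  if (is.null(probes)) probes <- wt_methyl_probes(fields_MHz = fields_MHz)
  .check_number(noise_fraction, "noise_fraction", lower = 0)
  structure(list(exch = exch, probes = probes, fields_MHz = fields_MHz,
                 noise_fraction = noise_fraction, seed = seed),
            class = "synthetic_truth")
}

#' Generate a noisy dispersion dataset from known parameters
#'
#' \eqn{R_{2,eff}} values are computed with the forward models at the
#' truth's parameters, perturbed with Gaussian noise of standard
#' deviation \code{noise_fraction * R2eff}, and given uncertainties via
#' [apply_error_floor()] of the generating noise.  Deterministic for a
#' fixed truth seed.
#'
#' @param truth A [synthetic_truth()].
#' @param schedule A [cpmg_schedule()] (or list of schedules, one per
#'   nucleus mode present).
#' @return A [dispersion_dataset()]; the generating seed is attached as
#'   attribute \code{"seed"}.
#' @export
gen_dispersion_dataset <- function(truth, schedule = cpmg_schedule("CH3_MQ")) {
  stopifnot(inherits(truth, "synthetic_truth"))
  scheds <- if (inherits(schedule, "cpmg_schedule")) list(schedule) else schedule
  names(scheds) <- vapply(scheds, `[[`, character(1), "nucleus_mode")
  if (!length(scheds)) .stopf("an empty schedule was supplied")
  rows <- .with_seed(truth$seed, {
    lapply(truth$probes, function(pr) {
      sch <- scheds[[pr$nucleus_mode]]
      if (is.null(sch))
        .stopf("no schedule for nucleus mode %s", pr$nucleus_mode)
      do.call(rbind, lapply(truth$fields_MHz, function(f) {
        y0 <- cpmg_r2eff(truth$exch, pr, f, sch$nu_list, sch$t_relax)
        sig_gen <- truth$noise_fraction * y0
        y <- rnorm(length(y0), y0, sig_gen)
        data.frame(probe_id = pr$probe_id, nucleus_mode = pr$nucleus_mode,
                   field_MHz = f, nu_cpmg = sch$nu_list, r2eff = y,
                   sigma = apply_error_floor(y0, sig_gen))
      }))
    })
  })
  t_relax <- .T_RELAX_DEFAULT
  for (m in names(scheds)) t_relax[[m]] <- scheds[[m]]$t_relax
  rs <- vapply(truth$probes, `[[`, numeric(1), "relative_sign")
  names(rs) <- vapply(truth$probes, `[[`, character(1), "probe_id")
  out <- dispersion_dataset(do.call(rbind, rows),
                            temperature = truth$exch$temperature,
                            t_relax = t_relax, relative_sign = rs)
  attr(out, "seed") <- truth$seed
  out
}

# local geometry of a toy residue: backbone plus an optional methyl
.toy_residue_atoms <- function(with_methyl) {
  if (with_methyl)
    data.frame(name = c("N", "CA", "C", "O", "CD1", "HD11", "HD12", "HD13"),
               resname = "ILE")
  else
    data.frame(name = c("N", "CA", "C", "O"), resname = "ALA")
}

.toy_place_residue <- function(ca, outward, with_methyl) {
  o <- outward / sqrt(sum(outward^2))
  up <- c(0, 0, 1)
  side <- c(o[2], -o[1], 0)
  xyz <- rbind(ca + 1.45 * side,               # N
               ca,                             # CA
               ca - 1.52 * side + 0.4 * up,    # C
               ca - 1.52 * side + 1.6 * up)    # O
  if (with_methyl) {
    cd <- ca + 2.5 * o
    h <- rbind(cd + 1.09 * c(0.94 * o[1], 0.94 * o[2], 0.33),
               cd + 1.09 * (0.94 * side + 0.33 * up),
               cd + 1.09 * c(0.94 * o[1] * 0.5 - 0.81 * side[1],
                             0.94 * o[2] * 0.5 - 0.81 * side[2], -0.33))
    xyz <- rbind(xyz, cd, h)
  }
  xyz
}

#' Two-conformation toy structural system
#'
#' A reproducible toy protein with a rigid helical core (identical in
#' both conformations) and a mobile segment whose conformation B is the
#' conformation-A segment rigidly displaced by a stated amount, so that
#' the core-fitted RMSD of the mobile segment between the states equals
#' the displacement.  Methyl-bearing residues (ILE CD1 with HD11--HD13
#' proton triplets) are placed throughout, so restraint evaluation
#' exercises pseudo-atom barycenters.
#'
#' @param n_core Core residues (\eqn{\ge} 10).
#' @param displacement Rigid displacement of the mobile segment in
#'   conformation B, \AA{}; positive.
#' @param n_mobile Mobile residues.
#' @param seed Seed controlling the reproducible placement jitter.
#' @return An object of class \code{"toy_system"}: atom table, the two
#'   coordinate sets \code{xyz_A}/\code{xyz_B}, and the core/mobile
#'   residue numbers.
#' @export
gen_toy_system <- function(n_core = 30, displacement = 20, n_mobile = 8,
                           seed = 1) {
  if (n_core < 10) .stopf("n_core must be >= 10 (got %d)", n_core)
  .check_number(displacement, "displacement", lower = 0, strict_lower = TRUE)
  .with_seed(seed, {
    atoms <- NULL
    xyz <- NULL
    n_tot <- n_core + n_mobile
    for (i in seq_len(n_tot)) {
      mobile <- i > n_core
      with_methyl <- (i %% 3 == 0) || mobile
      if (!mobile) {
        ang <- i * 100 * pi / 180
        ca <- c(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i) + rnorm(3, 0, 0.05)
        outward <- c(cos(ang), sin(ang), 0)
      } else {
        # mobile strand runs alongside the upper half of the core helix,
        # methyls pointing at the core, so that conformation B (shifted
        # down the helix axis) contacts a different set of core methyls
        k <- i - n_core
        ca <- c(6, 0, 1.5 * n_core - 17 + 1.8 * k) + rnorm(3, 0, 0.05)
        outward <- c(-1, 0, 0)
      }
      res_atoms <- .toy_residue_atoms(with_methyl)
      res_atoms$resno <- i
      atoms <- rbind(atoms, res_atoms)
      xyz <- rbind(xyz, .toy_place_residue(ca, outward, with_methyl))
    }
    atoms <- atoms[c("resno", "resname", "name")]
    mobile_rows <- atoms$resno > n_core
    shift <- c(0, 0, -displacement)
    xyz_b <- xyz
    xyz_b[mobile_rows, ] <- sweep(xyz[mobile_rows, , drop = FALSE], 2, shift, `+`)
    structure(list(atoms = atoms, xyz_A = xyz, xyz_B = xyz_b,
                   core_residues = seq_len(n_core),
                   mobile_residues = seq(n_core + 1, n_tot),
                   displacement = displacement, seed = seed),
              class = "toy_system")
  })
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("Toy two-state system: %d core + %d mobile residues, displacement %g A, seed %s\n",
              length(x$core_residues), length(x$mobile_residues),
              x$displacement, format(x$seed)))
  invisible(x)
}

#' Reference ensemble of a toy-system state
#'
#' \code{n_models} copies of one conformation with isotropic Gaussian
#' coordinate noise — a stand-in for a refined NMR bundle, suitable as
#' input to [build_violation_spec()] and [ward_cluster()].
#'
#' @param system A [gen_toy_system()] result.
#' @param state \code{"A"} or \code{"B"}.
#' @param n_models Number of members (20 by default).
#' @param coord_noise Per-coordinate Gaussian noise std, \AA{}.
#' @param seed RNG seed.
#' @return A [conformer_ensemble()].
#' @export
gen_reference_ensemble <- function(system, state = c("A", "B"),
                                   n_models = 20, coord_noise = 0.3,
                                   seed = 1) {
  stopifnot(inherits(system, "toy_system"))
  state <- match.arg(state)
  .check_number(coord_noise, "coord_noise", lower = 0)
  xyz <- if (state == "A") system$xyz_A else system$xyz_B
  .with_seed(seed, {
    models <- lapply(seq_len(n_models), function(i)
      xyz + matrix(rnorm(length(xyz), 0, coord_noise), ncol = 3))
    conformer_ensemble(models, system$atoms, label = state)
  })
}

#' Two-state jump trajectory of a toy system
#'
#' Frames follow a latent A/B telegraph process (per-frame switch
#' probability \code{p_switch}, or a single forced switch at
#' \code{switch_at}) with isotropic coordinate noise on top of the
#' current state's coordinates.  The latent state sequence is attached
#' as attribute \code{"latent_states"}.
#'
#' @param system A [gen_toy_system()] result.
#' @param n_frames Number of frames.
#' @param p_switch Per-frame switch probability in \eqn{[0, 1]}.
#' @param seed RNG seed.
#' @param start_state Starting state.
#' @param coord_noise Frame coordinate noise std, \AA{}.
#' @param switch_at Optional frame index of a single deterministic
#'   switch (overrides \code{p_switch}).
#' @return A [conformer_ensemble()] with frame times.
#' @export
gen_jump_trajectory <- function(system, n_frames = 100, p_switch = 0,
                                seed = 1, start_state = c("A", "B"),
                                coord_noise = 0.3, switch_at = NULL) {
  stopifnot(inherits(system, "toy_system"))
  start_state <- match.arg(start_state)
  .check_number(p_switch, "p_switch", lower = 0, upper = 1)
  .with_seed(seed, {
    states <- character(n_frames)
    cur <- start_state
    for (i in seq_len(n_frames)) {
      if (!is.null(switch_at)) {
        if (i == switch_at) cur <- setdiff(c("A", "B"), cur)
      } else if (i > 1 && runif(1) < p_switch) {
        cur <- setdiff(c("A", "B"), cur)
      }
      states[i] <- cur
    }
    models <- lapply(states, function(s) {
      xyz <- if (s == "A") system$xyz_A else system$xyz_B
      xyz + matrix(rnorm(length(xyz), 0, coord_noise), ncol = 3)
    })
    ens <- conformer_ensemble(models, system$atoms, label = "trajectory",
                              times = seq_len(n_frames))
    attr(ens, "latent_states") <- states
    ens
  })
}

#' State-specific methyl restraints of a toy system
#'
#' Intermethyl restraints that hold in one conformation but not the
#' other: methyl pairs whose barycenter distance is at most
#' \code{cutoff} in the chosen state and exceeds \code{cutoff + margin}
#' in the other.  Bounds are set to (2, \code{cutoff}) \AA{}.
#'
#' @param system A [gen_toy_system()] result.
#' @param state State in which the pairs are close.
#' @param cutoff Upper bound, \AA{}.
#' @param margin Required separation in the other state, \AA{}.
#' @return A [restraint_table()] (possibly empty).
#' @export
toy_state_restraints <- function(system, state = c("A", "B"), cutoff = 8,
                                 margin = 4) {
  stopifnot(inherits(system, "toy_system"))
  state <- match.arg(state)
  at <- system$atoms
  methyl_res <- unique(at$resno[at$name == "CD1"])
  prot <- "HD11;HD12;HD13"
  combs <- utils::combn(methyl_res, 2)
  keep <- list()
  for (k in seq_len(ncol(combs))) {
    ri <- combs[1, k]; rj <- combs[2, k]
    if (abs(ri - rj) < 2) next
    row <- restraint_table(ri, prot, rj, prot, lower = 2, upper = cutoff,
                           id = sprintf("%s_%d_%d", state, ri, rj),
                           state_tag = if (state == "A") "open_specific"
                                       else "closed_specific")
    d_a <- restraint_distance(system$xyz_A, at, row[1, ])
    d_b <- restraint_distance(system$xyz_B, at, row[1, ])
    d_in <- if (state == "A") d_a else d_b
    d_out <- if (state == "A") d_b else d_a
    if (d_in <= cutoff && d_out > cutoff + margin) keep[[length(keep) + 1]] <- row
  }
  if (!length(keep))
    return(.validate_restraints(restraint_table(1, prot, 3, prot, lower = 2,
                                                upper = cutoff)[0, ]))
  .validate_restraints(do.call(rbind, keep))
}
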