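.NUCLEUS_TOKENS <- c(N15SQ = "N15_SQ", CH3MQ = "CH3_MQ")
.DISP_HEADER <- "probe_id,nucleus,field_MHz,nu_cpmg_Hz,R2eff_s1,sigma_s1"

#' Write a dispersion dataset as CSV
#'
#' Comma-separated with header
#' \code{probe_id,nucleus,field_MHz,nu_cpmg_Hz,R2eff_s1,sigma_s1};
#' \code{nucleus} is \code{N15SQ} or \code{CH3MQ}.  Leading \code{#}
#' comment lines carry provenance (e.g. generator parameters and seed).
#'
#' @param data A [dispersion_dataset()].
#' @param path Output file.
#' @param comments Character vector of comment lines (without the
#'   leading \code{#}).
#' @return \code{path}, invisibly.
#' @export
write_dispersion_csv <- function(data, path, comments = NULL) {
  stopifnot(inherits(data, "dispersion_dataset"))
  pts <- data$points
  tok <- names(.NUCLEUS_TOKENS)[match(pts$nucleus_mode, .NUCLEUS_TOKENS)]
  if (is.null(comments) && !is.null(attr(data, "seed")))
    comments <- sprintf("generated by cpmgx, seed %s", format(attr(data, "seed")))
  lines <- c(if (length(comments)) paste("#", comments),
             .DISP_HEADER,
             sprintf("%s,%s,%.10g,%.10g,%.12g,%.12g", pts$probe_id, tok,
                     pts$field_MHz, pts$nu_cpmg, pts$r2eff, pts$sigma))
  writeLines(lines, path)
  invisible(path)
}

#' Read a dispersion dataset from CSV
#'
#' Strict reader for the format of [write_dispersion_csv()]: the header
#' must match exactly, nucleus tokens must be known, and malformed rows
#' are rejected with their line number.  Missing or non-positive sigma
#' values are replaced through [apply_error_floor()] from a dataset-level
#' noise figure (and reported).
#'
#' @param path Input file.
#' @param temperature Sample temperature (K) to attach.
#' @param t_relax Named relaxation periods per nucleus mode, s.
#' @param noise_figure Fractional noise used for missing uncertainties.
#' @return A [dispersion_dataset()].
#' @export
read_dispersion_csv <- function(path, temperature = 293,
                                t_relax = .T_RELAX_DEFAULT,
                                noise_figure = 0.02) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  lines <- raw[keep]
  if (!length(lines) || trimws(lines[1]) != .DISP_HEADER)
    .stopf("line %d: expected header '%s'", if (length(lineno)) lineno[1] else 1,
           .DISP_HEADER)
  body <- lines[-1]
  body_no <- lineno[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 6L)
  if (length(bad))
    .stopf("line %d: expected 6 comma-separated fields", body_no[bad[1]])
  m <- do.call(rbind, parts)
  nuc <- m[, 2]
  unknown <- which(!nuc %in% names(.NUCLEUS_TOKENS))
  if (length(unknown))
    .stopf("line %d: unknown nucleus token '%s'", body_no[unknown[1]],
           nuc[unknown[1]])
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(m[, col]))
    na_new <- which(is.na(v) & !(m[, col] %in% c("", "NA")))
    if (length(na_new))
      .stopf("line %d: malformed %s value '%s'", body_no[na_new[1]], name,
             m[na_new[1], col])
    v
  }
  pts <- data.frame(probe_id = m[, 1],
                    nucleus_mode = .NUCLEUS_TOKENS[nuc],
                    field_MHz = num(3, "field_MHz"),
                    nu_cpmg = num(4, "nu_cpmg_Hz"),
                    r2eff = num(5, "R2eff_s1"),
                    sigma = num(6, "sigma_s1"))
  fix <- is.na(pts$sigma) | pts$sigma <= 0
  if (any(fix)) {
    message(sum(fix), " row(s) without a valid sigma; applying the ",
            noise_figure * 100, "% error floor")
    pts$sigma[fix] <- apply_error_floor(pts$r2eff[fix], 0, noise_figure)
  }
  dispersion_dataset(pts, temperature = temperature, t_relax = t_relax)
}

.RESTRAINT_HEADER <- c("id", "resid_i", "atoms_i", "resid_j", "atoms_j",
                       "lower_A", "upper_A", "class", "state_tag")

#' Read/write restraint tables as TSV
#'
#' Tab-separated with header \code{id resid_i atoms_i resid_j atoms_j
#' lower_A upper_A class state_tag}; atom groups are semicolon-joined
#' atom names.
#'
#' @param restraints A [restraint_table()].
#' @param path File path.
#' @return \code{read_restraint_tsv} returns a [restraint_table()];
#'   \code{write_restraint_tsv} returns \code{path} invisibly.
#' @export
write_restraint_tsv <- function(restraints, path) {
  df <- as.data.frame(restraints)
  out <- data.frame(df$id, df$resid_i, df$atoms_i, df$resid_j, df$atoms_j,
                    df$lower, df$upper, df$class, df$state_tag)
  names(out) <- .RESTRAINT_HEADER
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_restraint_tsv
#' @export
read_restraint_tsv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.csv(path, sep = "\t", comment.char = "#",
                 stringsAsFactors = FALSE)
  miss <- setdiff(.RESTRAINT_HEADER, names(df))
  if (length(miss))
    .stopf("restraint TSV missing column(s): %s", paste(miss, collapse = ", "))
  names(df)[match(c("lower_A", "upper_A"), names(df))] <- c("lower", "upper")
  .validate_restraints(df[c("id", "resid_i", "atoms_i", "resid_j", "atoms_j",
                            "lower", "upper", "class", "state_tag")])
}

# expand CYANA-style pseudo-atom names (QD1 -> HD11;HD12;HD13)
.expand_pseudo <- function(name) {
  if (grepl("^Q", name))
    paste0(sub("^Q", "H", name), 1:3, collapse = ";")
  else name
}

#' Import CYANA-style upper-limit (.upl) restraints
#'
#' Reads simple \code{.upl} lines (\code{resno resname atom resno
#' resname atom upper_limit}); pseudo-atom names starting with \code{Q}
#' are expanded to their proton triplets.  Lower bounds are set to a
#' van-der-Waals floor of 1.8 \AA{}.
#'
#' @param path Input file.
#' @return A [restraint_table()].
#' @export
read_upl <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(raw[i]), "\\s+")[[1]]
    if (length(f) < 7)
      .stopf("line %d: expected 7 whitespace-separated fields in .upl", i)
    u <- suppressWarnings(as.numeric(f[7]))
    if (is.na(u)) .stopf("line %d: malformed upper limit '%s'", i, f[7])
    restraint_table(as.integer(f[1]), .expand_pseudo(f[3]),
                    as.integer(f[4]), .expand_pseudo(f[6]),
                    lower = 1.8, upper = u, id = sprintf("upl%03d", i))
  })
  out <- do.call(rbind, rows)
  out$class <- "upl"
  .validate_restraints(out)
}

#' Read a (multi-model) PDB file as a conformer ensemble
#'
#' Wraps \pkg{bio3d}'s PDB parser; MODEL/ENDMDL blocks become ensemble
#' members.  Files whose models do not share one atom table are
#' rejected, naming the first differing atom.
#'
#' @param path PDB file.
#' @param label Ensemble label (defaults to the file name).
#' @return A [conformer_ensemble()].
#' @export
read_multimodel_pdb <- function(path, label = basename(path)) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  raw <- readLines(path)
  starts <- grep("^MODEL", raw)
  if (length(starts) > 1) {
    ends <- grep("^ENDMDL", raw)
    if (length(ends) != length(starts))
      .stopf("unbalanced MODEL/ENDMDL records in %s", path)
    keys <- lapply(seq_along(starts), function(k) {
      blk <- raw[seq(starts[k], ends[k])]
      blk <- blk[grepl("^(ATOM|HETATM)", blk)]
      substr(blk, 13, 27)  # atom name, resname, chain, resno
    })
    for (k in seq_along(keys)[-1]) {
      if (length(keys[[k]]) != length(keys[[1]]))
        .stopf("model %d has %d atoms but model 1 has %d", k,
               length(keys[[k]]), length(keys[[1]]))
      diffidx <- which(keys[[k]] != keys[[1]])
      if (length(diffidx))
        .stopf("model %d differs from model 1 at atom %d ('%s' vs '%s')",
               k, diffidx[1], trimws(keys[[k]][diffidx[1]]),
               trimws(keys[[1]][diffidx[1]]))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(resno = pdb$atom$resno, resname = pdb$atom$resid,
                      name = pdb$atom$elety)
  xyz <- pdb$xyz
  models <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  conformer_ensemble(models, atoms, label = label)
}

#' Write a conformer ensemble as a multi-model PDB
#'
#' @param ens A [conformer_ensemble()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_multimodel_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "conformer_ensemble"))
  xyz <- do.call(rbind, lapply(ens$models, function(m) as.vector(t(m))))
  bio3d::write.pdb(file = path, xyz = xyz, resno = ens$atoms$resno,
                   resid = ens$atoms$resname, elety = ens$atoms$name)
  invisible(path)
}

#' Strict run-configuration reader
#'
#' Flat INI-style key-value file with \code{[section]} headers.  Unknown
#' sections or keys are rejected outright, preventing silently ignored
#' misconfiguration.
#'
#' Recognized sections/keys: \code{[global]} \code{temperature},
#' \code{seed}; \code{[fit]} \code{rex_min}, \code{kex_min},
#' \code{kex_max}, \code{kex_nodes}, \code{p_min}, \code{p_max},
#' \code{p_nodes}, \code{mc_repeats}; \code{[selections]}
#' \code{fit_residues}, \code{measure_residues} (range lists like
#' \code{"40-97,137-220"}); \code{[restraints]} \code{tolerance};
#' \code{[trajectory]} \code{eps_stable}, \code{eps_arrive},
#' \code{eps_depart}, \code{window}, \code{final_fraction}.
#'
#' @param path Config file.
#' @return Nested named list of class \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  known <- list(
    global = c("temperature", "seed"),
    fit = c("rex_min", "kex_min", "kex_max", "kex_nodes", "p_min", "p_max",
            "p_nodes", "mc_repeats"),
    selections = c("fit_residues", "measure_residues"),
    restraints = c("tolerance"),
    trajectory = c("eps_stable", "eps_arrive", "eps_depart", "window",
                   "final_fraction"))
  if (!file.exists(path)) .stopf("file not found: %s", path)
  raw <- readLines(path)
  cfg <- list()
  section <- NULL
  for (i in seq_along(raw)) {
    line <- trimws(sub("#.*$", "", raw[i]))
    if (!nzchar(line)) next
    if (grepl("^\\[.*\\]$", line)) {
      section <- sub("^\\[(.*)\\]$", "\\1", line)
      if (!section %in% names(known))
        .stopf("line %d: unknown config section [%s]", i, section)
      next
    }
    if (is.null(section)) .stopf("line %d: key outside any [section]", i)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) .stopf("line %d: expected key = value", i)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% known[[section]])
      .stopf("line %d: unknown key '%s' in section [%s]", i, key, section)
    if (section == "selections") {
      cfg[[section]][[key]] <- parse_residue_ranges(val)
    } else {
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v)) .stopf("line %d: malformed numeric value '%s'", i, val)
      cfg[[section]][[key]] <- v
    }
  }
  structure(cfg, class = "run_config")
}

#' Parse a residue-range list like "40-97,137-220"
#' @param text Range specification.
#' @return Integer vector of residue numbers.
#' @export
parse_residue_ranges <- function(text) {
  parts <- strsplit(gsub("\\s", "", text), ",", fixed = TRUE)[[1]]
  out <- unlist(lapply(parts, function(p) {
    if (grepl("^\\d+-\\d+$", p)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      seq(ab[1], ab[2])
    } else if (grepl("^\\d+$", p)) {
      as.integer(p)
    } else .stopf("malformed residue range '%s'", p)
  }))
  sort(unique(out))
}
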