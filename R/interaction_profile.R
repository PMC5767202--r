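# Rule-based typing of protein-ligand contacts per MD frame and per-residue
# interaction-frequency profiles.
#
# Frames are supplied as an annotated atom table; donor/acceptor/hydrophobe
# roles are input metadata from structure preparation, not perceived here.
# The geometric thresholds are explicit configuration: hydrogen bond =
# donor-heavy-atom to acceptor distance <= 0.35 nm and donor-H...acceptor
# angle (vertex at the hydrogen) >= 120 degrees; hydrophobic contact =
# apolar carbon-carbon distance <= 0.40 nm. A residue scores at most once
# per interaction type per frame.

#' Default interaction-typing rules
#'
#' @param hbond_distance donor-heavy-atom to acceptor cutoff, nm.
#' @param hbond_angle minimum donor-H...acceptor angle, degrees.
#' @param hydrophobic_distance apolar carbon-carbon cutoff, nm.
#' @return Named list of rule parameters.
#' @export
interaction_rules <- function(hbond_distance = 0.35, hbond_angle = 120,
                              hydrophobic_distance = 0.40) {
  stopifnot(hbond_distance > 0, hydrophobic_distance > 0,
            hbond_angle >= 0, hbond_angle <= 180)
  list(hbond_distance = hbond_distance, hbond_angle = hbond_angle,
       hydrophobic_distance = hydrophobic_distance)
}

FRAME_COLUMNS <- c("frame", "side", "residue", "atom", "element",
                   "x", "y", "z", "is_donor", "is_acceptor", "is_hydrophobe",
                   "bonded_to")

check_frame_table <- function(atoms) {
  miss <- setdiff(FRAME_COLUMNS, names(atoms))
  if (length(miss))
    stop("frame table missing annotation column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!atoms$side %in% c("ligand", "protein"))
  if (length(bad))
    stop("side must be 'ligand' or 'protein' (row ", bad[1L], ")")
  invisible(atoms)
}

vec_angle_deg <- function(v1, v2) {
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# contacts between one donor table (with its hydrogens) and one acceptor table
hbond_pairs <- function(donors, hydrogens, acceptors, rules) {
  hits <- character(0)
  for (i in seq_len(nrow(donors))) {
    d <- donors[i, ]
    hs <- hydrogens[hydrogens$bonded_to == d$atom, , drop = FALSE]
    if (nrow(hs) == 0L)
      stop("donor atom '", d$atom, "' has no bonded hydrogen in the frame table")
    for (j in seq_len(nrow(acceptors))) {
      a <- acceptors[j, ]
      dist <- sqrt((d$x - a$x)^2 + (d$y - a$y)^2 + (d$z - a$z)^2)
      if (dist > rules$hbond_distance) next
      for (k in seq_len(nrow(hs))) {
        h <- hs[k, ]
        ang <- vec_angle_deg(c(d$x - h$x, d$y - h$y, d$z - h$z),
                             c(a$x - h$x, a$y - h$y, a$z - h$z))
        if (ang >= rules$hbond_angle) {
          hits <- c(hits, if (d$side == "protein") d$residue else a$residue)
          break
        }
      }
    }
  }
  unique(hits)
}

#' Classify protein-ligand contacts in one frame
#'
#' @param atoms data.frame for a single frame with columns `frame`, `side`
#'   (ligand/protein), `residue`, `atom` (unique id within the frame),
#'   `element`, `x`, `y`, `z` (nm), logical `is_donor`, `is_acceptor`,
#'   `is_hydrophobe`, and `bonded_to` (heavy-atom id for hydrogens, NA
#'   otherwise).
#' @param rules an [interaction_rules()] list.
#' @return data.frame with columns `residue`, `type` (`hbond` /
#'   `hydrophobic`), at most one row per residue and type.
#' @export
classify_frame <- function(atoms, rules = interaction_rules()) {
  check_frame_table(atoms)
  heavy <- atoms[atoms$element != "H", , drop = FALSE]
  hydro <- atoms[atoms$element == "H", , drop = FALSE]
  lig <- heavy[heavy$side == "ligand", , drop = FALSE]
  prot <- heavy[heavy$side == "protein", , drop = FALSE]

  res_h <- unique(c(
    hbond_pairs(lig[lig$is_donor, , drop = FALSE],
                hydro[hydro$side == "ligand", , drop = FALSE],
                prot[prot$is_acceptor, , drop = FALSE], rules),
    hbond_pairs(prot[prot$is_donor, , drop = FALSE],
                hydro[hydro$side == "protein", , drop = FALSE],
                lig[lig$is_acceptor, , drop = FALSE], rules)))

  lc <- lig[lig$is_hydrophobe & lig$element == "C", , drop = FALSE]
  pc <- prot[prot$is_hydrophobe & prot$element == "C", , drop = FALSE]
  res_phob <- character(0)
  if (nrow(lc) && nrow(pc)) {
    for (j in seq_len(nrow(pc))) {
      dmin <- min(sqrt((lc$x - pc$x[j])^2 + (lc$y - pc$y[j])^2 +
                       (lc$z - pc$z[j])^2))
      if (dmin <= rules$hydrophobic_distance)
        res_phob <- c(res_phob, pc$residue[j])
    }
    res_phob <- unique(res_phob)
  }

  out <- rbind(
    if (length(res_h)) data.frame(residue = res_h, type = "hbond",
                                  stringsAsFactors = FALSE),
    if (length(res_phob)) data.frame(residue = res_phob, type = "hydrophobic",
                                     stringsAsFactors = FALSE))
  if (is.null(out)) out <- data.frame(residue = character(0),
                                      type = character(0),
                                      stringsAsFactors = FALSE)
  out
}

#' Per-residue interaction-frequency profile over a trajectory
#'
#' For every residue and interaction type, the fraction of frames in which at
#' least one contact of that type occurs. Frequencies are invariant under
#' frame reordering.
#'
#' @param frames data.frame in the [classify_frame()] format covering all
#'   frames (distinguished by the `frame` column).
#' @param rules an [interaction_rules()] list.
#' @return An object of class `interaction_profile`: a residue x type
#'   frequency matrix with attributes `n_frames` and `rules`.
#' @export
interaction_profile <- function(frames, rules = interaction_rules()) {
  check_frame_table(frames)
  per_frame <- lapply(split(frames, frames$frame), classify_frame,
                      rules = rules)
  n_frames <- length(per_frame)
  all_res <- unique(unlist(lapply(per_frame, function(d) d$residue)))
  all_res <- c(all_res,
               setdiff(unique(frames$residue[frames$side == "protein"]),
                       all_res))
  types <- c("hbond", "hydrophobic")
  freq <- matrix(0, nrow = length(all_res), ncol = length(types),
                 dimnames = list(all_res, types))
  for (d in per_frame) {
    for (i in seq_len(nrow(d)))
      freq[d$residue[i], d$type[i]] <- freq[d$residue[i], d$type[i]] + 1
  }
  freq <- freq / n_frames
  structure(freq, n_frames = n_frames, rules = rules,
            class = c("interaction_profile", "matrix"))
}

#' @export
print.interaction_profile <- function(x, ...) {
  cat(sprintf("<interaction_profile> %d residue(s) x %d type(s) over %d frame(s)\n",
              nrow(x), ncol(x), attr(x, "n_frames")))
  print(unclass(x))
  invisible(x)
}

#' Display table for profile figures
#'
#' Hydrophobic contacts are typically far more abundant than directed
#' interactions; for stacked-bar display their frequencies are divided by an
#' arbitrary factor (10 by default). Other columns pass through unchanged.
#'
#' @param profile an [interaction_profile()].
#' @param hydrophobic_divisor display divisor for the hydrophobic column.
#' @return data.frame with `residue`, `hbond`, `hydrophobic` columns.
#' @export
display_table <- function(profile, hydrophobic_divisor = 10) {
  stopifnot(inherits(profile, "interaction_profile"), hydrophobic_divisor > 0)
  data.frame(residue = rownames(profile),
             hbond = unname(profile[, "hbond"]),
             hydrophobic = unname(profile[, "hydrophobic"]) /
               hydrophobic_divisor,
             stringsAsFactors = FALSE)
}

#' Stacked-bar plot of an interaction profile
#'
#' @param x an [interaction_profile()].
#' @param hydrophobic_divisor display divisor applied before plotting.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.interaction_profile <- function(x, hydrophobic_divisor = 10, ...) {
  tab <- display_table(x, hydrophobic_divisor)
  m <- t(as.matrix(tab[, c("hbond", "hydrophobic")]))
  colnames(m) <- tab$residue
  graphics::barplot(m, horiz = TRUE, las = 1,
                    legend.text = c("hydrogen bond",
                                    sprintf("hydrophobic / %g",
                                            hydrophobic_divisor)),
                    xlab = "interaction frequency", ...)
  invisible(x)
}
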