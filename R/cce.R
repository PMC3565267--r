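# Characteristic-crystallographic-element (CCE) norm: per-site structural
# similarity to hcp, fcc and fivefold reference environments, the thresholded
# order parameters S^X and the crystallinity tau_c = S^hcp + S^fcc.

default_templates <- function() {
  list(hcp = make_template("hcp"), fcc = make_template("fcc"),
       fivefold = make_template("fivefold"))
}

#' CCE norm of explicit shell vectors
#'
#' Low-level entry point: the norm of an arbitrary set of first-shell
#' vectors against one template, minimized over rigid rotations.  Shell
#' vectors are normalized internally to unit mean length (radial
#' sensitivity is retained through their relative lengths).
#'
#' @param shell Matrix of neighbour vectors (rows), one per template vector.
#' @param template A [make_template()] object.
#' @return The non-negative norm; 0 exactly for a perfect shell.
#' @export
cce_shell <- function(shell, template) {
  shell <- as.matrix(shell)
  if (nrow(shell) != nrow(template$vectors)) {
    stop("shell must have one vector per template direction")
  }
  d <- sqrt(rowSums(shell^2))
  cce_shell_cpp(shell / mean(d), template$vectors, template$symmetry_ops)
}

#' Per-site CCE norms
#'
#' For each requested site, takes its 12 nearest minimum-image neighbours,
#' scales the shell to unit mean distance, and minimizes over rotations the
#' combined cost of (i) optimal assignment onto the template shell and (ii)
#' self-mismatch under the template's distinguishing symmetry operations.
#' The norm is invariant to global rotation, translation and uniform
#' dilation, zero only for a perfect first shell, and strongly
#' discriminating between the reference structures.  Sites with fewer than
#' 12 available neighbours receive `Inf` and are counted as amorphous.
#'
#' @param sys A `chain_system`.
#' @param sites Site indices to evaluate (default all).
#' @param templates Named list of [make_template()] objects.
#' @param k_nn First-shell size (default 12, matching the templates).
#' @return Data frame: `site_id` and one `eps_<name>` column per template.
#' @export
cce_norm <- function(sys, sites = seq_len(n_atoms(sys)),
                     templates = default_templates(), k_nn = 12) {
  m <- cce_cpp(sys$pos, sys$box$L, as.integer(sites) - 1L,
               lapply(templates, `[[`, "vectors"),
               lapply(templates, `[[`, "symmetry_ops"), k_nn)
  out <- data.frame(site_id = as.integer(sites))
  nm <- names(templates)
  nm[nm == "fivefold"] <- "5f"
  for (j in seq_along(templates)) out[[paste0("eps_", nm[j])]] <- m[, j]
  out
}

#' Classify every site of a frame and compute the order parameters
#'
#' A site is assigned to the structure of its smallest norm if that norm
#' lies below the threshold, and is amorphous otherwise.  The order
#' parameter `S_X` is the fraction of sites with `eps_X` below the
#' threshold (the empirical mass of the norm distribution below
#' `eps_thres`), and the crystallinity is `tau_c = S_hcp + S_fcc`.
#'
#' @param sys A `chain_system`.
#' @param threshold Norm threshold `eps_thres` (default 0.245).
#' @param templates Named list of templates.
#' @param sites Sites to classify (default all; fractions use these sites).
#' @return List with `sites` (data frame of norms and `label`) and `order`
#'   (list `S_hcp`, `S_fcc`, `S_5f`, `tau_c`, `n_sites`, `threshold`).
#' @export
classify_frame <- function(sys, threshold = 0.245,
                           templates = default_templates(),
                           sites = seq_len(n_atoms(sys))) {
  norms <- cce_norm(sys, sites, templates)
  epcols <- grep("^eps_", names(norms), value = TRUE)
  structs <- sub("^eps_", "", epcols)
  em <- as.matrix(norms[epcols])
  best <- apply(em, 1, which.min)
  bestval <- em[cbind(seq_len(nrow(em)), best)]
  norms$label <- ifelse(is.finite(bestval) & bestval < threshold,
                        structs[best], "amorphous")
  S <- vapply(epcols, function(cn) mean(norms[[cn]] < threshold), numeric(1))
  names(S) <- paste0("S_", structs)
  order <- as.list(S)
  order$tau_c <- sum(S[names(S) %in% c("S_hcp", "S_fcc")])
  order$n_sites <- nrow(norms)
  order$threshold <- threshold
  list(sites = norms, order = order)
}

#' Norm distributions P(eps^X)
#'
#' Normalized histograms of the finite per-site norms, one per structure.
#' The integral of each histogram below the threshold reproduces `S_X`
#' within binning error; infinite sentinel norms are excluded from the
#' histogram but retained in the `S_X` denominators by [classify_frame()].
#'
#' @param norms Data frame from [cce_norm()] or [classify_frame()]`$sites`.
#' @param breaks Histogram breaks (norm units).
#' @return Data frame: `structure`, `mid`, `density`, `count`.
#' @export
norm_distribution <- function(norms, breaks = seq(0, 2, by = 0.02)) {
  epcols <- grep("^eps_", names(norms), value = TRUE)
  if (length(epcols) == 0) stop("no norm columns present")
  out <- NULL
  for (cn in epcols) {
    x <- norms[[cn]]
    x <- x[is.finite(x)]
    if (length(x) == 0) {
      warning("all norms infinite for ", cn, "; empty histogram")
      next
    }
    x <- pmin(x, max(breaks))  # overflow mass into the last bin
    h <- hist(x, breaks = breaks, plot = FALSE)
    out <- rbind(out, data.frame(structure = sub("^eps_", "", cn),
                                 mid = h$mids, density = h$density,
                                 count = h$counts))
  }
  out
}

#' Colour map for rendering classified sites
#'
#' The conventional rendering scheme: hcp blue, fcc red, fivefold green;
#' amorphous sites are usually omitted.
#'
#' @param labels Character vector of site labels.
#' @return Character vector of colour names (`NA` for amorphous).
#' @export
label_colors <- function(labels) {
  c(hcp = "blue", fcc = "red", `5f` = "green", amorphous = NA)[labels]
}
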