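# Gasteiger-Marsili electronegativity parameters (a, b, c) by atom class.
# chi(q) = a + b q + c q^2; the cation electronegativity a + b + c scales the
# charge transferred across each bond (hydrogen uses the special value 20.02).
.peoe_params <- list(
  H     = c(7.17, 6.24, -0.56),
  C.sp3 = c(7.98, 9.18, 1.88),
  C.sp2 = c(8.79, 9.32, 1.51),
  C.sp  = c(10.39, 9.45, 0.73),
  N.sp3 = c(11.54, 10.82, 1.36),
  N.sp2 = c(12.87, 11.15, 0.85),
  N.sp  = c(15.68, 11.70, -0.27),
  O.sp3 = c(14.18, 12.92, 1.39),
  O.sp2 = c(17.07, 13.79, 0.47),
  F     = c(14.66, 13.85, 2.31),
  Cl    = c(11.00, 9.69, 1.35),
  Br    = c(10.08, 8.47, 1.16),
  I     = c(9.90, 7.96, 0.96),
  S.sp3 = c(10.14, 9.13, 1.38),
  P.sp3 = c(8.90, 8.24, 0.96)
)

# classify every heavy atom of a mol_graph into a PEOE parameter class
peoe_atom_class <- function(mol) {
  n <- n_atoms(mol)
  cls <- character(n)
  ords <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    o <- if (isTRUE(mol$bonds$aromatic[k])) 1.5 else mol$bonds$order[k]
    ords[[mol$bonds$i[k]]] <- c(ords[[mol$bonds$i[k]]], o)
    ords[[mol$bonds$j[k]]] <- c(ords[[mol$bonds$j[k]]], o)
  }
  # neighbors' multiple-bond participation, for conjugation perception
  has_multiple <- vapply(seq_len(n), function(a) any(ords[[a]] >= 1.5),
                         logical(1))
  nbrs <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    nbrs[[mol$bonds$i[k]]] <- c(nbrs[[mol$bonds$i[k]]], mol$bonds$j[k])
    nbrs[[mol$bonds$j[k]]] <- c(nbrs[[mol$bonds$j[k]]], mol$bonds$i[k])
  }
  for (a in seq_len(n)) {
    el <- mol$atoms$element[a]
    o <- ords[[a]]
    hyb <- if (any(o == 3) || sum(o == 2) >= 2) "sp" else
      if (any(o >= 1.5)) "sp2" else "sp3"
    # lone-pair N/O adjacent to a multiple bond is conjugated (amide N,
    # carboxyl/ester O, aniline N): treated as sp2
    if (hyb == "sp3" && el %in% c("N", "O") &&
        any(has_multiple[nbrs[[a]]])) {
      hyb <- "sp2"
    }
    cls[a] <- switch(el,
      C = paste0("C.", hyb),
      N = paste0("N.", hyb),
      O = if (hyb == "sp") "O.sp2" else paste0("O.", hyb),
      S = "S.sp3",
      P = "P.sp3",
      F = "F", Cl = "Cl", Br = "Br", I = "I",
      H = "H",
      abort(sprintf("element %s is outside the PEOE parameter set", el),
            class = "sibcut_error_unsupported_element")
    )
  }
  cls
}

#' Gasteiger PEOE partial charges
#'
#' Iterative partial equalization of orbital electronegativities over the
#' full molecular graph (hydrogens are reinstated as explicit iteration
#' nodes, then folded back onto their heavy neighbor). Six iterations with a
#' damping factor halving each round, the standard schedule.
#'
#' @param mol A [mol_graph()].
#' @param n_iter Number of equalization iterations (default 6).
#' @return A numeric vector of per-heavy-atom partial charges (hydrogen
#'   charges folded in); sums to the molecule's net formal charge.
#' @export
compute_peoe_charges <- function(mol, n_iter = 6L) {
  n <- n_atoms(mol)
  cls_heavy <- peoe_atom_class(mol)
  # expand explicit hydrogens
  hc <- mol$atoms$h_count
  nh <- sum(hc)
  cls <- c(cls_heavy, rep("H", nh))
  owner <- integer(0)
  bonds <- mol$bonds[, c("i", "j")]
  hidx <- n
  hb_i <- integer(nh); hb_j <- integer(nh)
  pos <- 0L
  for (a in seq_len(n)) {
    if (hc[a] > 0) for (u in seq_len(hc[a])) {
      hidx <- hidx + 1L; pos <- pos + 1L
      hb_i[pos] <- a; hb_j[pos] <- hidx
      owner <- c(owner, a)
    }
  }
  bi <- c(bonds$i, hb_i); bj <- c(bonds$j, hb_j)
  par <- .peoe_params[cls]
  av <- map_dbl(par, 1); bv <- map_dbl(par, 2); cv <- map_dbl(par, 3)
  chi_plus <- av + bv + cv
  chi_plus[cls == "H"] <- 20.02
  q <- c(as.numeric(mol$atoms$charge), rep(0, nh))
  damp <- 1
  for (it in seq_len(n_iter)) {
    damp <- damp * 0.5
    chi <- av + bv * q + cv * q^2
    dq <- numeric(length(q))
    for (k in seq_along(bi)) {
      i <- bi[k]; j <- bj[k]
      if (chi[j] > chi[i]) {
        d <- (chi[j] - chi[i]) / chi_plus[i]
        dq[i] <- dq[i] + d; dq[j] <- dq[j] - d
      } else if (chi[i] > chi[j]) {
        d <- (chi[i] - chi[j]) / chi_plus[j]
        dq[j] <- dq[j] + d; dq[i] <- dq[i] - d
      }
    }
    q <- q + damp * dq
  }
  folded <- q[seq_len(n)]
  if (nh > 0) {
    for (p in seq_len(nh)) folded[owner[p]] <- folded[owner[p]] + q[n + p]
  }
  folded
}
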