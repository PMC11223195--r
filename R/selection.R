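# Atom selection helpers (internal).

## Indices of atoms matching the given fields; any NULL field matches all.
.selectAtoms <- function(atoms, chain = NULL, resno = NULL, elety = NULL) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  if (!is.null(resno)) keep <- keep & atoms$resno %in% resno
  if (!is.null(elety)) keep <- keep & atoms$elety %in% elety
  which(keep)
}

## Single-atom lookup; errors name the missing residue/atom.
.atomIndex <- function(atoms, chain, resno, elety) {
  idx <- .selectAtoms(atoms, chain = chain, resno = resno, elety = elety)
  if (length(idx) == 0L)
    stop(sprintf("selection error: no atom '%s' in residue %s of chain %s",
                 elety, resno, chain))
  if (length(idx) > 1L)
    stop(sprintf("selection error: atom '%s' in residue %s of chain %s is not unique",
                 elety, resno, chain))
  idx
}

.atomsOf <- function(x) {
  if (is(x, "TrajectoryWindow")) x@topology@atoms
  else if (is(x, "ComplexTopology")) x@atoms
  else if (is(x, "Assembly")) x@atoms
  else stop("cannot extract an atom table from a ", class(x)[1])
}
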