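# Minimal PDB ATOM-record writer for synthetic structure fixtures.

pdb_atom <- function(serial, name, resn, chain, resno, x, y, z,
                     alt = "", occ = 1.00, elem = NULL) {
  if (is.null(elem)) elem <- substr(name, 1, 1)
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resn, chain, resno, x, y, z, occ, 0, elem)
}

pdb_doc <- function(...) c(..., "END")
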