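Optional external fixtures (not redistributed with the package)
===============================================================

Two validation suites reproduce published case-study numbers on
real-world datasets that cannot be bundled here. To enable them, place
the following plain-text files in this directory:

  michael_strike.net   Michael's (1997) strike sociogram: 24 nodes,
                       38 edges, Pajek format, with node labels
                       including "Bob", "Norm", "Sam", "Wendle".

  ekman_yeast.net      Giant component of the Ekman et al. (2006)
                       high-fidelity yeast protein-protein interaction
                       network: 2,444 nodes, 6,271 edges, Pajek format,
                       ORF names as labels.

  party_hubs.txt       63 consensus party hubs, one ORF per line.
  date_hubs.txt        145 consensus date hubs, one ORF per line.

Without these files the corresponding validation tests report failure
(missing data), while every property-based suite runs as normal.
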