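Package: nosscan
Title: Screening Protein Crystal Structures for Overlooked NOS Linkages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate nitrogen-oxygen-sulfur (NOS) covalent linkages
    that were modeled as non-bonded contacts in deposited protein crystal
    structures. Reads mmCIF/PDB coordinate files, companion BDB files with
    consistent isotropic B-factors, and wwPDB validation reports; screens
    sulfur-nitrogen contacts through resolution, distance, occupancy and RSRZ
    quality filters; extracts fifteen geometric, B-factor, packing and
    solvent-accessibility descriptors per contact pair; and searches all
    descriptor subsets with low-dimensional embedding (UMAP), mean-shift
    clustering, Silhouette gating and reference-linkage containment to label
    contact pairs as probable or improbable NOS-bond candidates. Includes a
    synthetic fixture generator that plants contacts with known geometry,
    occupancy, B-factor and RSRZ values, and descriptor matrices with known
    cluster structure, so every stage can be validated against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    cluster,
    stats,
    tools,
    utils,
    uwot,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
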