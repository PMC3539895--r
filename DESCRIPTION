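Package: molconsist
Title: Consistency Auditing of Systematic Chemical Identifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Audits the internal and cross-database consistency of systematic
    chemical identifiers (MOL blocks, SMILES, InChI, IUPAC names). Every
    identifier channel is normalised to a Standard InChI and compared against
    the MOL-derived reference, with and without FICTS structure
    standardisation (fragment stripping, isotope clearing, charge
    neutralisation, tautomer canonicalisation, stereochemistry removal).
    Includes a between-database cross-reference audit with multiplicity
    breakdown, and a self-verifying synthetic database generator that injects
    identifier inconsistencies of known classes at known rates for method
    validation. Structure-level chemistry is delegated to RDKit (which embeds
    the IUPAC InChI implementation) through a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, yaml
SystemRequirements: Python (>= 3.8) with the rdkit package on the PATH as
    'python'; OpenBabel ('obabel') optionally used as an independent oracle
    in the test suite.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
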