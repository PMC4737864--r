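# Target-network definitions over the 90-region AAL parcellation (1-based
# indices).  Edit or replace this file (see load_target_networks) to redefine
# the sets; every name must map to a non-empty list of indices in 1..90.
#
# "DMN" is the in-text definition (medial prefrontal 23-26, posterior
# cingulate/precuneus 35,36,67,68, bilateral inferior parietal 61,62).
# "DMN_table1" is the published table's variant, which differs from the
# in-text list.  "insula_cingulate_table1" reproduces the published row
# verbatim even though it prints the same indices as the DMN row (flagged as
# a likely typesetting error; see the package vignette).
DMN: [23, 24, 25, 26, 35, 36, 67, 68, 61, 62]
DMN_table1: [3, 24, 25, 26, 35, 36, 37, 68, 61, 62]
frontal_lobe: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 51, 52]
temporal_lobe: [37, 38, 39, 40, 41, 42, 55, 56, 79, 80, 81, 82, 83, 84, 85, 86, 87, 88, 89, 90]
occipital_lobe: [43, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53, 54]
parietal_lobe: [57, 58, 59, 60, 61, 62, 63, 64, 65, 66, 67, 68]
insula_cingulate_table1: [3, 24, 25, 26, 35, 36, 37, 68, 61, 62]
central: [71, 72, 73, 74, 75, 76, 77, 78]
limbic: [37, 38, 39, 40, 41, 42]
# Edge-lesioning building blocks: hippocampal/parahippocampal sets and the
# striatum (caudate + putamen; pallidum excluded by default -- add 75, 76
# here if your definition of striatum includes it).
HC: [37, 38, 39, 40]
HC_left: [37, 39]
HC_right: [38, 40]
striatum: [71, 72, 73, 74]
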