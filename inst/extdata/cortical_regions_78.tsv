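region	structural_degree
Precuneus R	20
Precuneus L	19
Middle Occipital Gyrus L	17
Superior Frontal Gyrus, medial R	13
Calcarine fissure and surrounding cortex L	13
Middle Temporal Gyrus L	13
Superior Occipital Gyrus R	13
Calcarine fissure and surrounding cortex R	13
Precentral Gyrus L	13
Lingual Gyrus R	12
Superior Frontal Gyrus, medial L	12
Middle Occipital Gyrus R	12
Precentral Gyrus R	12
Postcentral Gyrus L	11
Superior Frontal Gyrus, dorsal L	11
Postcentral Gyrus R	11
Superior Frontal Gyrus, dorsal R	11
Superior Temporal Gyrus R	10
Supplementary motor area R	10
Cuneus R	10
Superior Occipital Gyrus.L	10
Insula L	9
Inferior Temporal Gyrus L	9
Lingual Gyrus L	9
Supplementary motor area L	9
Supramarginal Gyrus R	9
Angular gyrus R	9
Middle Temporal Gyrus R	9
Fusiform Gyrus L	9
Superior Parietal Gyrus R	9
Middle Frontal Gyrus, R	9
Inferior Frontal Gyrus, orbital part L	9
Anterior Cingulate and paracingulate Gyri L	9
Cuneus L	9
Superior Frontal Gyrus, medial orbital R	8
Angular gyrus L	8
Superior Parietal Gyrus L	8
Inferior Frontal Gyrus, opercular part.R	8
Superior Frontal Gyrus, orbital part L	8
Superior Temporal Gyrus L	8
Middle Frontal Gyrus L	8
Temporal Pole: middle temporal gyrus R	8
Paracentral Lobule L	8
Anterior Cingulate and paracingulate gyri R	8
Fusiform Gyrus R	8
Superior Frontal Gyrus, medial orbital L	7
Median Cingulate and paracingulate gyri R	7
Inferior Occipital Gyrus L	7
Paracentral Lobule R	7
Inferior Frontal Gyrus, opercular part L	7
Supramarginal Gyrus L	7
Gyrus Rectus L	7
Rolandic operculum L	7
Inferior Frontal Gyrus, triangular part L	7
Superior Frontal Gyrus, orbital part R	7
Inferior Parietal L	7
Inferior Temporal Gyrus R	7
Inferior Occipital Gyrus R	6
Olfactory cortex R	6
Parahippocampal Gyrus L	6
Temporal Pole: middle temporal gyrus L	6
Inferior Parietal R	6
Median Cingulate and paracingulate gyri L	6
Parahippocampal Gyrus R	6
Rolandic operculum R	6
Posterior cingulate Gyrus L	6
Inferior Frontal Gyrus triangular part R	6
Inferior Frontal Gyrus, orbital part R	5
Insula R	5
Temporal Pole: superior temporal gyrus L	5
Middle Frontal Gyrus, orbital part L	5
Posterior Cingulate Gyrus R	5
Middle Frontal Gyrus, orbital part R	4
Gyrus Rectus R	4
Olfactory cortex L	4
Temporal Pole: superior temporal gyrus R	3
Heschl Gyrus L	2
Heschl Gyrus R	1
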