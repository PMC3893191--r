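# Amino-acid biosynthesis pathway models: one row per (amino_acid, route,
# step, KO); KOs sharing a step index are interchangeable (isozymes or
# alternative orthologs). Step lists are condensed single-route summaries of
# the standard KEGG modules for amino-acid biosynthesis (e.g. M00016 lysine/
# DAP, M00017 methionine, M00018 threonine, M00019 valine-isoleucine, M00020
# serine, M00023 tryptophan, M00026 histidine, M00432 leucine); they are a
# packaged static fixture, not live pathway-database queries. essential:
# yes = obligate vertebrate-essential, conditional = essential in some
# vertebrates (Arg/His), no = non-essential.
amino_acid	route	step	ko	essential
Ala	1	1	K00814	no
Arg	1	1	K00611	conditional
Arg	1	2	K01940	conditional
Arg	1	3	K01755	conditional
Asn	1	1	K01953	no
Asp	1	1	K00812	no
Asp	1	1	K00813	no
Cys	1	1	K00789	no
Cys	1	2	K01251	no
Cys	1	3	K01697	no
Cys	1	4	K01758	no
Gln	1	1	K01915	no
Glu	1	1	K00261	no
Glu	1	1	K00262	no
Gly	1	1	K00600	no
His	1	1	K00765	conditional
His	1	2	K01523	conditional
His	1	3	K01814	conditional
His	1	4	K02500	conditional
His	1	4	K02501	conditional
His	1	5	K01693	conditional
His	1	6	K00817	conditional
His	1	7	K00013	conditional
Ile	1	1	K01754	yes
Ile	1	2	K01652	yes
Ile	1	2	K01653	yes
Ile	1	3	K00053	yes
Ile	1	4	K01687	yes
Ile	1	5	K00826	yes
Leu	1	1	K01649	yes
Leu	1	2	K01703	yes
Leu	1	3	K01704	yes
Leu	1	4	K00052	yes
Leu	1	5	K00826	yes
Lys	1	1	K00928	yes
Lys	1	2	K00133	yes
Lys	1	3	K01714	yes
Lys	1	4	K00215	yes
Lys	1	5	K01778	yes
Lys	1	6	K01586	yes
Met	1	1	K00928	yes
Met	1	2	K00133	yes
Met	1	3	K00003	yes
Met	1	4	K00651	yes
Met	1	5	K01739	yes
Met	1	6	K01760	yes
Met	1	7	K00548	yes
Met	1	7	K00549	yes
Phe	1	1	K01626	yes
Phe	1	2	K01735	yes
Phe	1	3	K03785	yes
Phe	1	4	K00014	yes
Phe	1	5	K00891	yes
Phe	1	6	K00800	yes
Phe	1	7	K01736	yes
Phe	1	8	K01850	yes
Phe	1	9	K04518	yes
Phe	1	10	K00832	yes
Pro	1	1	K00931	no
Pro	1	2	K00147	no
Pro	1	3	K00286	no
Ser	1	1	K00058	no
Ser	1	2	K00831	no
Ser	1	3	K01079	no
Thr	1	1	K00928	yes
Thr	1	2	K00133	yes
Thr	1	3	K00003	yes
Thr	1	4	K00872	yes
Thr	1	5	K01733	yes
Trp	1	1	K01657	yes
Trp	1	2	K00766	yes
Trp	1	3	K01609	yes
Trp	1	4	K01695	yes
Trp	1	5	K01696	yes
Tyr	1	1	K00500	no
Val	1	1	K01652	yes
Val	1	1	K01653	yes
Val	1	2	K00053	yes
Val	1	3	K01687	yes
Val	1	4	K00826	yes
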