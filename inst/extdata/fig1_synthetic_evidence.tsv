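gene	missense	cis_eqtl	go_bp	go_cc	go_mf	kegg
ARID5B	TRUE	TRUE	TRUE	TRUE	TRUE	FALSE
SP4	FALSE	TRUE	TRUE	TRUE	TRUE	FALSE
ZNF222	FALSE	TRUE	TRUE	TRUE	TRUE	FALSE
ZNF223	FALSE	TRUE	TRUE	TRUE	TRUE	FALSE
ORMDL3	FALSE	TRUE	TRUE	TRUE	TRUE	FALSE
IKZF1	FALSE	TRUE	TRUE	TRUE	TRUE	FALSE
GATA3	TRUE	FALSE	TRUE	TRUE	TRUE	FALSE
CEBPE	FALSE	TRUE	TRUE	TRUE	TRUE	FALSE
SLC7A8	TRUE	FALSE	TRUE	TRUE	TRUE	FALSE
CDKN2A	FALSE	TRUE	TRUE	TRUE	TRUE	FALSE
LHPP	FALSE	FALSE	TRUE	TRUE	TRUE	TRUE
PIP4K2A	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE
CCDC26	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE
ELK3	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE
GPATCH2L	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE
OR5AL1	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE
OR5AL2P	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE
PDE4B	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE
RNU6-366P	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE
CPSF2	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE
TP63	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE
CSGALNACT1	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE
INTS10	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE
DDC	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE
FIGNL1	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE
ERG	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE
AGBL1	TRUE	FALSE	FALSE	TRUE	TRUE	FALSE
PTPRJ	FALSE	TRUE	FALSE	TRUE	TRUE	FALSE
RN7SL361P	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE
BCL11A	FALSE	FALSE	FALSE	TRUE	TRUE	TRUE
RNU6-1091P	FALSE	FALSE	FALSE	TRUE	TRUE	FALSE
RPL6P5	FALSE	FALSE	FALSE	TRUE	TRUE	FALSE
ALLG01	FALSE	FALSE	FALSE	TRUE	TRUE	FALSE
ALLG02	TRUE	FALSE	FALSE	FALSE	TRUE	FALSE
ALLG03	FALSE	TRUE	FALSE	FALSE	TRUE	FALSE
ALLG04	FALSE	FALSE	TRUE	FALSE	TRUE	FALSE
ALLG05	FALSE	FALSE	FALSE	TRUE	TRUE	FALSE
ALLG06	FALSE	FALSE	FALSE	FALSE	TRUE	TRUE
ALLG07	TRUE	FALSE	FALSE	FALSE	TRUE	FALSE
ALLG08	FALSE	TRUE	FALSE	FALSE	TRUE	FALSE
ALLG09	FALSE	FALSE	TRUE	FALSE	TRUE	FALSE
ALLG10	FALSE	FALSE	FALSE	TRUE	TRUE	FALSE
ALLG11	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE
ALLG12	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE
ALLG13	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE
ALLG14	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE
ALLG15	FALSE	FALSE	FALSE	FALSE	FALSE	TRUE
ALLG16	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
ALLG17	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE
ALLG18	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE
ALLG19	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE
ALLG20	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE
ALLG21	FALSE	FALSE	FALSE	FALSE	FALSE	TRUE
ALLG22	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
ALLG23	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
ALLG24	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
ALLG25	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
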