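# Putative organisations of protein-coding and rRNA genes of hypothetical
# ancestral mitochondrial genomes (10 distinct gene orders).
HTU_01	cox1 cox2 atp8 atp6 cox3 nad3 -nad5 -nad4 -nad4L nad6 cob rrnS rrnL nad1 nad2
HTU_02	cox1 cox2 atp8 atp6 -nad5 -nad4 -nad4L nad6 cob rrnS rrnL nad1 cox3 nad3 nad2
HTU_03	cox1 cox2 atp8 atp6 -nad5 -nad4 -nad4L nad6 cob -nad3 -cox3 rrnS rrnL nad1 nad2
HTU_04	cox1 cox2 atp8 atp6 nad6 cob nad4L nad4 nad5 -nad3 -cox3 rrnS rrnL nad1 nad2
HTU_05	cox1 cox2 atp8 atp6 cox3 nad3 -nad5 -nad4 -nad4L -cob -nad6 -nad1 -rrnL -rrnS nad2
HTU_06	cox1 cox2 atp8 atp6 cox3 nad3 nad4L nad4 nad5 -nad6 cob -nad1 -rrnL -rrnS nad2
HTU_07	cox1 cox2 atp8 atp6 -nad5 -nad4 -nad4L nad6 cob -nad1 -rrnL -rrnS cox3 nad3 nad2
HTU_08	cox1 cox2 atp8 atp6 cox3 nad3 -nad5 -nad4 -nad4L -cob nad6 rrnS rrnL nad1 nad2
HTU_09	cox1 cox2 atp8 atp6 cox3 nad3 rrnS rrnL nad1 -cob nad6 -nad5 -nad4 -nad4L nad2
HTU_10	cox1 cox2 atp8 atp6 cox3 nad3 rrnS rrnL nad1 nad6 cob nad4L nad4 nad5 nad2
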