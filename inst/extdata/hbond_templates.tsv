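residue_name	atom_name	role	hydrogens
ALA	N	donor	H
ALA	O	acceptor	
ARG	N	donor	H
ARG	O	acceptor	
ARG	NE	donor	HE
ARG	NH1	donor	HH11,HH12
ARG	NH2	donor	HH21,HH22
ASN	N	donor	H
ASN	O	acceptor	
ASN	OD1	acceptor	
ASN	ND2	donor	HD21,HD22
ASP	N	donor	H
ASP	O	acceptor	
ASP	OD1	acceptor	
ASP	OD2	acceptor	
CYS	N	donor	H
CYS	O	acceptor	
CYS	SG	donor	HG
GLN	N	donor	H
GLN	O	acceptor	
GLN	OE1	acceptor	
GLN	NE2	donor	HE21,HE22
GLU	N	donor	H
GLU	O	acceptor	
GLU	OE1	acceptor	
GLU	OE2	acceptor	
GLY	N	donor	H
GLY	O	acceptor	
HIS	N	donor	H
HIS	O	acceptor	
HIS	ND1	both	HD1
HIS	NE2	both	HE2
ILE	N	donor	H
ILE	O	acceptor	
LEU	N	donor	H
LEU	O	acceptor	
LYS	N	donor	H
LYS	O	acceptor	
LYS	NZ	donor	HZ1,HZ2,HZ3
MET	N	donor	H
MET	O	acceptor	
MET	SD	acceptor	
PHE	N	donor	H
PHE	O	acceptor	
PRO	O	acceptor	
SER	N	donor	H
SER	O	acceptor	
SER	OG	both	HG
THR	N	donor	H
THR	O	acceptor	
THR	OG1	both	HG1
TRP	N	donor	H
TRP	O	acceptor	
TRP	NE1	donor	HE1
TYR	N	donor	H
TYR	O	acceptor	
TYR	OH	both	HH
VAL	N	donor	H
VAL	O	acceptor	
A	O1P	acceptor	
A	O2P	acceptor	
A	OP1	acceptor	
A	OP2	acceptor	
A	O3'	acceptor	
A	O5'	acceptor	
A	O4'	acceptor	
A	O2'	both	HO2'
A	N1	acceptor	
A	N3	acceptor	
A	N7	acceptor	
A	N6	donor	H61,H62
G	O1P	acceptor	
G	O2P	acceptor	
G	OP1	acceptor	
G	OP2	acceptor	
G	O3'	acceptor	
G	O5'	acceptor	
G	O4'	acceptor	
G	O2'	both	HO2'
G	N3	acceptor	
G	N7	acceptor	
G	O6	acceptor	
G	N1	donor	H1
G	N2	donor	H21,H22
C	O1P	acceptor	
C	O2P	acceptor	
C	OP1	acceptor	
C	OP2	acceptor	
C	O3'	acceptor	
C	O5'	acceptor	
C	O4'	acceptor	
C	O2'	both	HO2'
C	O2	acceptor	
C	N3	acceptor	
C	N4	donor	H41,H42
U	O1P	acceptor	
U	O2P	acceptor	
U	OP1	acceptor	
U	OP2	acceptor	
U	O3'	acceptor	
U	O5'	acceptor	
U	O4'	acceptor	
U	O2'	both	HO2'
U	O2	acceptor	
U	O4	acceptor	
U	N3	donor	H3
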