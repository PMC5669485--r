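# Head percolation rules (condensed Collins table).
# Format: PARENT direction child-priority-list
# For each category in priority order, children are scanned in the given
# direction; the first match supplies the head. With no match the first
# child in scan direction is the head; unknown parents default to the
# rightmost child.
S left TO IN VP S SBAR ADJP UCP NP
SINV left VBZ VBD VBP VB MD VP S SINV ADJP NP
SBAR left WHNP WHPP WHADVP WHADJP IN DT S SQ SINV SBAR FRAG
SQ left VBZ VBD VBP VB MD VP SQ
VP left TO VBD VBN MD VBZ VB VBG VBP VP ADJP NN NNS NP
NP right NN NNP NNPS NNS NX POS JJR NP ADJP PRN
NX right NN NNP NNPS NNS NX
PP left IN TO VBG VBN RP FW
ADJP left NNS QP NN ADVP JJ VBN VBG ADJP JJR NP JJS DT FW RBR RBS SBAR RB
ADVP right RB RBR RBS FW ADVP TO CD JJR JJ IN NP JJS NN
QP left IN NNS NN JJ RB DT CD QP JJR JJS
WHNP right WDT WP WP$ WHADJP WHPP WHNP
WHPP left IN TO FW
PRN left S NP PP
CONJP right CC RB IN
FRAG right
UCP right
X right
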