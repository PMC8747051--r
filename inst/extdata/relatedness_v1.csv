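code_a,code_b,r
adopted,adopted,0
adopted,niece_nephew,0
adopted,non_relative,0
adopted,other_relative,0
adopted,unspecified,0
child,adopted,0
child,child,0.5
child,child_in_law,0
child,grandchild,0.25
child,niece_nephew,0.125
child,non_relative,0
child,other_relative,0.125
child,parent,0.25
child,parent_in_law,0.25
child,sibling,0.125
child,unspecified,0
child_in_law,adopted,0
child_in_law,child_in_law,0
child_in_law,grandchild,0.25
child_in_law,niece_nephew,0
child_in_law,non_relative,0
child_in_law,other_relative,0
child_in_law,parent,0
child_in_law,parent_in_law,0
child_in_law,sibling,0
child_in_law,unspecified,0
grandchild,adopted,0
grandchild,grandchild,0.25
grandchild,niece_nephew,0.125
grandchild,non_relative,0
grandchild,other_relative,0
grandchild,parent,0.125
grandchild,parent_in_law,0.125
grandchild,sibling,0.125
grandchild,unspecified,0
head,adopted,0
head,child,0.5
head,child_in_law,0
head,grandchild,0.25
head,head,0
head,niece_nephew,0.125
head,non_relative,0
head,other_relative,0.125
head,parent,0.5
head,parent_in_law,0
head,sibling,0.5
head,spouse,0
head,unspecified,0
niece_nephew,niece_nephew,0.25
niece_nephew,non_relative,0
niece_nephew,unspecified,0
non_relative,non_relative,0
non_relative,unspecified,0
other_relative,niece_nephew,0.125
other_relative,non_relative,0
other_relative,other_relative,0.125
other_relative,unspecified,0
parent,adopted,0
parent,niece_nephew,0.25
parent,non_relative,0
parent,other_relative,0.125
parent,parent,0
parent,parent_in_law,0
parent,sibling,0.5
parent,unspecified,0
parent_in_law,adopted,0
parent_in_law,niece_nephew,0
parent_in_law,non_relative,0
parent_in_law,other_relative,0
parent_in_law,parent_in_law,0
parent_in_law,sibling,0
parent_in_law,unspecified,0
sibling,adopted,0
sibling,niece_nephew,0.25
sibling,non_relative,0
sibling,other_relative,0.125
sibling,sibling,0.5
sibling,unspecified,0
spouse,adopted,0
spouse,child,0.5
spouse,child_in_law,0
spouse,grandchild,0.25
spouse,niece_nephew,0
spouse,non_relative,0
spouse,other_relative,0
spouse,parent,0
spouse,parent_in_law,0.5
spouse,sibling,0
spouse,spouse,0
spouse,unspecified,0
unspecified,unspecified,0
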